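test_that("single-gene statistics are exact", {
  p <- profile_from_motifs("s", list(c("AAA", "ACC", "ACG", "ACT", "AGA")))
  st <- motif_stats(p)
  expect_identical(st$n_unique_motifs, 1L)
  expect_identical(st$n_genes, 1L)
  expect_identical(st$mean_size, 5)
  expect_identical(st$sd_size, 0)
  expect_identical(st$size_histogram$motif_size, 5L)
  expect_identical(st$size_histogram$n_genes, 1L)
})

test_that("union counts and genes-per-motif follow the shared-motif accounting", {
  # two species sharing exactly one motif, each with two unique motifs
  p1 <- profile_from_motifs("s1", list("AAA", c("CCC", "GGG")))
  p2 <- profile_from_motifs("s2", list("AAA", "TTT"))
  st <- motif_stats(list(p1, p2))
  expect_identical(st$n_unique_motifs, 3L)
  expect_identical(st$n_genes, 4L)
  expect_equal(glance(st)$genes_per_motif, 4 / 3, tolerance = 1e-12)
  # spectrum: AAA occurs twice, the other two once each
  expect_identical(st$repetition_spectrum$occurrences, c(1L, 2L))
  expect_identical(st$repetition_spectrum$n_motifs, c(2L, 1L))
})

test_that("genes using all codons produce empty motifs and zero frequencies", {
  full <- seq_averting(character(0))
  genes <- tibble::tibble(species = "s", sequence = rep(full, 3))
  p <- build_species_profile(genes, species = "s")
  st <- motif_stats(p)
  expect_identical(st$size_histogram,
                   tibble::tibble(motif_size = 0L, n_genes = 3L))
  expect_identical(unique(st$per_symbol_freq$frequency), 0)
  expect_identical(st$mean_size, 0)
})

test_that("per-symbol aversion frequency is the per-species gene fraction", {
  p <- profile_from_motifs("s", list("AAA", c("AAA", "CCC"), "GGG", "GGG"))
  st <- motif_stats(p)
  freq <- setNames(st$per_symbol_freq$frequency, st$per_symbol_freq$symbol)
  expect_identical(unname(freq["AAA"]), 2 / 4)
  expect_identical(unname(freq["CCC"]), 1 / 4)
  expect_identical(unname(freq["GGG"]), 2 / 4)
  expect_identical(unname(freq["TTT"]), 0)
  # a codon averted by every gene has frequency 1
  q <- profile_from_motifs("t", list(c("TAT", "AAA"), c("TAT", "CCC")))
  stq <- motif_stats(q)
  fq <- setNames(stq$per_symbol_freq$frequency, stq$per_symbol_freq$symbol)
  expect_identical(unname(fq["TAT"]), 1)
})

test_that("shared/singleton partition the unique motif set", {
  distinct <- profile_from_motifs("a", list("AAA", "CCC", "GGG"))
  sv <- shared_vs_unique(distinct)
  expect_identical(sv$n_shared, 0L)
  expect_identical(sv$n_singleton, 3L)

  mono <- profile_from_motifs("b", list("TTT", "TTT", "TTT"))
  sv2 <- shared_vs_unique(mono)
  expect_identical(sv2$n_shared, 1L)
  expect_identical(sv2$n_singleton, 0L)

  # constructed mix, hand-counted: AAA x3 (two species), CCC x1, GGG x2, TTT x1
  p1 <- profile_from_motifs("s1", list("AAA", "AAA", "CCC", "GGG"))
  p2 <- profile_from_motifs("s2", list("AAA", "GGG", "TTT"))
  sv3 <- shared_vs_unique(list(p1, p2))
  expect_identical(sv3$n_shared, 2L)
  expect_identical(sv3$n_singleton, 2L)
  expect_identical(sv3$n_shared + sv3$n_singleton, sv3$n_unique_motifs)
})

test_that("summary invariants hold on random profiles and duplicates never shrink", {
  set.seed(77)
  pool <- lapply(1:25, function(i) sample(cam_codons(), sample(1:6, 1)))
  for (rep in 1:10) {
    sets1 <- sample(pool, sample(3:10, 1), replace = TRUE)
    sets2 <- sample(pool, sample(3:10, 1), replace = TRUE)
    ps <- list(profile_from_motifs("s1", sets1),
               profile_from_motifs("s2", sets2))
    st <- motif_stats(ps)
    expect_identical(sum(st$size_histogram$n_genes), st$n_genes)
    expect_identical(sum(st$repetition_spectrum$n_motifs), st$n_unique_motifs)
    expect_equal(
      sum(st$size_histogram$motif_size * st$size_histogram$n_genes) /
        st$n_genes,
      st$mean_size, tolerance = 1e-9)
    expect_true(all(st$per_symbol_freq$frequency >= 0 &
                      st$per_symbol_freq$frequency <= 1))
    sv <- shared_vs_unique(ps)
    expect_identical(sv$n_shared + sv$n_singleton, st$n_unique_motifs)

    # duplicating a gene never changes the union, never decreases n_shared
    dup <- profile_from_motifs("s1", c(sets1, sets1[1]))
    st_dup <- motif_stats(list(dup, ps[[2]]))
    sv_dup <- shared_vs_unique(list(dup, ps[[2]]))
    expect_identical(st_dup$n_unique_motifs, st$n_unique_motifs)
    expect_gte(sv_dup$n_shared, sv$n_shared)
  }
})

test_that("mixing codon and amino-acid profiles is rejected and TSVs are written", {
  pc <- profile_from_motifs("s1", list("AAA"))
  pa <- pc
  pa$mode <- "amino_acid"
  expect_error(motif_stats(list(pc, pa)), class = "camphy_mode_mismatch")

  dir <- tempfile()
  write_motif_stats(motif_stats(pc), dir)
  expect_setequal(list.files(dir),
                  c("size_histogram.tsv", "per_symbol_freq.tsv",
                    "repetition_spectrum.tsv", "summary.tsv"))
  tab <- read.delim(file.path(dir, "size_histogram.tsv"))
  expect_identical(tab$n_genes, 1L)
})
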