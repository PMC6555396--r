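#' Configuration for the codon-aversion simulator
#'
#' The simulator is a test harness emulating the one statistical
#' assumption the method rests on: codon aversion is heritable, so
#' closely related species share more motifs than distant ones. An
#' ancestral genome of `n_genes` genes is given per-gene aversion sets
#' (each non-start codon excluded independently with probability
#' `aversion_rate`; at least one stop codon is always kept usable).
#' Aversion sets are then copied down `tree`; on each branch each gene
#' is perturbed with probability `min(1, flip_rate * branch_length)` by
#' adding or removing one uniformly chosen eligible codon. Leaves are
#' realized as CDS whose codons are drawn from the complement of the
#' aversion set, with every non-averted codon guaranteed to appear at
#' least once so the realized motif equals the intended set exactly.
#'
#' @param tree An [ape::phylo] tree (4 or more leaves) with branch
#'   lengths, or a Newick string.
#' @param n_genes Genes per genome.
#' @param gene_length_range Min/max gene length in codons (min 10);
#'   must accommodate the largest possible non-averted codon set.
#' @param aversion_rate Expected fraction of the codon table excluded
#'   per ancestral gene, in `[0, 1]`.
#' @param flip_rate Per-unit-branch-length probability of one
#'   gain/loss event per gene, in `[0, 1]` per unit length.
#' @param seed Integer seed; mandatory, for byte-identical output.
#' @return A `cam_sim_config` list.
#' @export
sim_config <- function(tree, n_genes = 100, gene_length_range = c(80, 150),
                       aversion_rate = 0.23, flip_rate = 0.15, seed) {
  if (is.character(tree)) tree <- read_newick(tree)
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) < 4L) {
    abort("Simulation tree needs at least 4 leaves.", class = "camphy_usage")
  }
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    abort("Simulation tree needs branch lengths on every edge.",
          class = "camphy_usage")
  }
  if (missing(seed) || !is.numeric(seed)) {
    abort("A numeric seed is mandatory.", class = "camphy_usage")
  }
  stopifnot(n_genes >= 1, length(gene_length_range) == 2L,
            gene_length_range[1] >= 10,
            gene_length_range[1] <= gene_length_range[2],
            aversion_rate >= 0, aversion_rate <= 1,
            flip_rate >= 0, flip_rate <= 1)
  structure(
    list(tree = tree, n_genes = as.integer(n_genes),
         gene_length_range = as.integer(gene_length_range),
         aversion_rate = aversion_rate, flip_rate = flip_rate,
         seed = as.integer(seed)),
    class = "cam_sim_config"
  )
}

# one aversion set: exclude non-start codons independently, keep >= 1 stop
sample_aversion_set <- function(aversion_rate) {
  eligible <- setdiff(cam_codons(), cam_start_codon())
  averted <- eligible[stats::runif(length(eligible)) < aversion_rate]
  stops <- cam_stop_codons()
  if (all(stops %in% averted)) {
    averted <- setdiff(averted, sample(stops, 1L))
  }
  sort(averted)
}

# CDS realizing exactly this aversion set: one copy of every usable codon
# plus uniform draws, in random order
realize_gene <- function(averted, length_range) {
  usable <- setdiff(cam_codons(), averted)
  len <- sample(seq(length_range[1], length_range[2]), 1L)
  if (len < length(usable)) {
    abort(sprintf("Gene length %d cannot cover %d usable codons.",
                  len, length(usable)),
          class = "camphy_config_error")
  }
  extra <- sample(usable, len - length(usable), replace = TRUE)
  paste(sample(c(usable, extra)), collapse = "")
}

#' Sample an ancestral genome
#'
#' Draws the per-gene aversion sets of the ancestor and realizes each
#' gene as a CDS (see [sim_config()] for the model). Mainly useful on
#' its own for closure tests; [evolve_along_tree()] runs the full
#' simulation.
#'
#' @param config A `cam_sim_config`.
#' @return A list with `aversion_sets` (list of sorted codon vectors)
#'   and `sequences` (character vector of CDS).
#' @export
simulate_ancestor <- function(config) {
  stopifnot(inherits(config, "cam_sim_config"))
  withr::with_seed(config$seed, {
    sets <- replicate(config$n_genes,
                      sample_aversion_set(config$aversion_rate),
                      simplify = FALSE)
    seqs <- vapply(sets, realize_gene, character(1),
                   length_range = config$gene_length_range)
    list(aversion_sets = sets, sequences = seqs)
  })
}

perturb_set <- function(averted, p_event) {
  if (stats::runif(1) >= p_event) return(averted)
  usable <- setdiff(cam_codons(), averted)
  stops_usable <- intersect(usable, cam_stop_codons())
  protected <- cam_start_codon()
  if (length(stops_usable) == 1L) protected <- c(protected, stops_usable)
  can_gain <- setdiff(usable, protected)     # codons that may become averted
  can_lose <- averted                        # codons that may become used
  if (length(can_gain) > 0L && (length(can_lose) == 0L ||
                                stats::runif(1) < 0.5)) {
    sort(c(averted, sample(can_gain, 1L)))
  } else if (length(can_lose) > 0L) {
    setdiff(averted, sample(can_lose, 1L))
  } else {
    averted
  }
}

#' Evolve codon aversion along a tree
#'
#' Runs the full generative model of [sim_config()]: ancestral aversion
#' sets evolve down the tree by single-codon gain/loss events, and each
#' leaf is realized as a CDS genome whose per-gene motifs equal the
#' leaf's aversion sets exactly.
#'
#' @param config A `cam_sim_config`.
#' @return A `cam_sim` object: `tree` (the true tree), `species` (named
#'   list with per-leaf `aversion_sets` and `sequences`), and `config`.
#' @export
evolve_along_tree <- function(config) {
  stopifnot(inherits(config, "cam_sim_config"))
  tree <- stats::reorder(config$tree, "cladewise")
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  withr::with_seed(config$seed, {
    sets_at <- vector("list", n_tip + tree$Nnode)
    sets_at[[root]] <- replicate(config$n_genes,
                                 sample_aversion_set(config$aversion_rate),
                                 simplify = FALSE)
    for (e in seq_len(nrow(tree$edge))) {
      parent <- tree$edge[e, 1]; child <- tree$edge[e, 2]
      p_event <- min(1, config$flip_rate * tree$edge.length[e])
      sets_at[[child]] <- lapply(sets_at[[parent]], perturb_set, p_event)
    }
    species <- lapply(seq_len(n_tip), function(tip) {
      sets <- sets_at[[tip]]
      seqs <- vapply(sets, realize_gene, character(1),
                     length_range = config$gene_length_range)
      list(aversion_sets = sets, sequences = seqs)
    })
    names(species) <- tree$tip.label
    structure(list(tree = config$tree, species = species, config = config),
              class = "cam_sim")
  })
}

#' @export
print.cam_sim <- function(x, ...) {
  cat(sprintf("<cam_sim> %d species x %d genes (seed %d)\n",
              length(x$species), x$config$n_genes, x$config$seed))
  invisible(x)
}

#' Species profiles straight from a simulation
#'
#' Extracts motifs from the realized CDS of every simulated species via
#' the regular motif machinery, i.e. the same code path real FASTA input
#' takes after parsing.
#'
#' @param sim A `cam_sim` object.
#' @return Named list of `cam_profile` objects.
#' @export
sim_profiles <- function(sim) {
  stopifnot(inherits(sim, "cam_sim"))
  genes <- purrr::map_dfr(names(sim$species), function(sp) {
    tibble(species = sp,
           gene_id = sprintf("g%04d", seq_along(sim$species[[sp]]$sequences)),
           sequence = sim$species[[sp]]$sequences)
  })
  species_profiles(genes, mode = "codon")
}

#' Write a simulation to disk
#'
#' One FASTA file per leaf species, the true tree as
#' `true_tree.newick`, and the true per-gene motif sets as
#' `true_motifs.tsv` (species, gene, comma-joined motif).
#'
#' @param sim A `cam_sim` object.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "cam_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sp in names(sim$species)) {
    seqs <- sim$species[[sp]]$sequences
    lines <- as.vector(rbind(
      sprintf(">g%04d [gene=g%04d]", seq_along(seqs), seq_along(seqs)),
      seqs))
    writeLines(lines, file.path(dir, paste0(sp, ".fasta")))
  }
  write_newick(sim$tree, file.path(dir, "true_tree.newick"))
  motifs <- purrr::map_dfr(names(sim$species), function(sp) {
    sets <- sim$species[[sp]]$aversion_sets
    tibble(species = sp,
           gene = sprintf("g%04d", seq_along(sets)),
           motif = vapply(sets, motif_key, character(1)))
  })
  utils::write.table(motifs, file.path(dir, "true_motifs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
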