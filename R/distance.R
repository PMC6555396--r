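#' Pairwise distance between two species motif profiles
#'
#' The distance between species A and B with motif sets `a` and `b` is
#' one minus the overlap coefficient,
#' `1 - |a intersect b| / min(|a|, |b|)`,
#' so species sharing most of their motifs are close and species sharing
#' none are at the maximum distance of 1. When the shared fraction falls
#' below `min_overlap` (default 5%) the overlap is deemed uninformative
#' -- a handful of coincidental matches between a small genome and a
#' large one should not look like signal -- and the distance is clamped
#' to exactly 1. Consequently no value ever falls strictly between
#' `1 - min_overlap` and 1.
#'
#' @param a,b `cam_profile` objects of the same mode.
#' @param min_overlap Minimum shared fraction below which the distance
#'   is clamped to 1. Set to 0 to disable the rule.
#' @return A single distance in `[0, 1]`.
#' @examples
#' genes <- tibble::tibble(species = "A", sequence = c("AAATTT", "AAA"))
#' # see cam_distance_matrix() for a full pipeline example
#' @export
cam_distance <- function(a, b, min_overlap = 0.05) {
  stopifnot(inherits(a, "cam_profile"), inherits(b, "cam_profile"))
  if (!identical(a$mode, b$mode)) {
    abort(sprintf("Profile mode mismatch: %s vs %s.", a$mode, b$mode),
          class = "camphy_mode_mismatch")
  }
  if (length(a$motifs) == 0L || length(b$motifs) == 0L) {
    abort("Profile with an empty motif set.", class = "camphy_invalid_profile")
  }
  stopifnot(min_overlap >= 0, min_overlap <= 1)
  shared <- length(intersect(a$motifs, b$motifs)) /
    min(length(a$motifs), length(b$motifs))
  if (shared < min_overlap) 1.0 else 1.0 - shared
}

#' Distance matrix over a set of species profiles
#'
#' Computes [cam_distance()] for every unordered pair of profiles. The
#' result is a symmetric matrix with zero diagonal, labelled in input
#' order, of class `cam_dist`.
#'
#' @param profiles List of `cam_profile` objects (3 or more) with unique
#'   species labels, e.g. from [species_profiles()].
#' @inheritParams cam_distance
#' @return A `cam_dist`: a labelled symmetric numeric matrix.
#' @export
cam_distance_matrix <- function(profiles, min_overlap = 0.05) {
  stopifnot(is.list(profiles))
  if (length(profiles) < 3L) {
    abort("At least 3 species profiles are required.", class = "camphy_usage")
  }
  labels <- vapply(profiles, function(p) p$species, character(1))
  dup <- unique(labels[duplicated(labels)])
  if (length(dup) > 0L) {
    abort(paste0("Duplicate species labels: ", paste(dup, collapse = ", ")),
          class = "camphy_duplicate_labels")
  }
  n <- length(profiles)
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      d <- cam_distance(profiles[[i]], profiles[[j]], min_overlap)
      m[i, j] <- d
      m[j, i] <- d
    }
  }
  class(m) <- c("cam_dist", class(m))
  m
}

#' Tidy a distance matrix into pair rows
#'
#' @param x A `cam_dist` matrix.
#' @param ... Unused.
#' @return Tibble with one row per unordered species pair: `species_a`,
#'   `species_b`, `distance`.
#' @method tidy cam_dist
#' @export
tidy.cam_dist <- function(x, ...) {
  labels <- rownames(x)
  idx <- which(upper.tri(x), arr.ind = TRUE)
  tibble(
    species_a = labels[idx[, 1]],
    species_b = labels[idx[, 2]],
    distance = x[idx]
  )
}

#' @export
print.cam_dist <- function(x, ...) {
  cat(sprintf("<cam_dist> %d species\n", nrow(x)))
  print(unclass(x), digits = 4)
  invisible(x)
}

format_distance <- function(d) sprintf("%.6f", d)

#' Write a distance matrix
#'
#' The native dialect is self-describing: a header row of tab-separated
#' species labels, then one row per species (label + tab-separated
#' distances to 6 decimal places). The PHYLIP dialect starts with the
#' species count and pads/truncates labels to 10 characters.
#'
#' @param m A `cam_dist` (or plain labelled symmetric matrix).
#' @param path Output file path or a connection; default standard output.
#' @param dialect `"native"` or `"phylip"`.
#' @return The text lines, invisibly.
#' @export
write_cam_matrix <- function(m, path = stdout(),
                             dialect = c("native", "phylip")) {
  dialect <- match.arg(dialect)
  labels <- rownames(m)
  if (dialect == "native") {
    lines <- c(
      paste(c("species", labels), collapse = "\t"),
      vapply(seq_along(labels), function(i) {
        paste(c(labels[i], format_distance(m[i, ])), collapse = "\t")
      }, character(1))
    )
  } else {
    short <- substr(labels, 1L, 10L)
    dup <- unique(short[duplicated(short)])
    if (length(dup) > 0L) {
      clash <- labels[short %in% dup]
      abort(paste0("PHYLIP labels collide after 10-character truncation: ",
                   paste(clash, collapse = ", ")),
            class = "camphy_phylip_collision")
    }
    lines <- c(
      as.character(length(labels)),
      vapply(seq_along(labels), function(i) {
        paste0(formatC(short[i], width = -10L), " ",
               paste(format_distance(m[i, ]), collapse = " "))
      }, character(1))
    )
  }
  writeLines(lines, path)
  invisible(lines)
}

#' Read a distance matrix
#'
#' Parses the native or square PHYLIP dialect written by
#' [write_cam_matrix()]. Asymmetries within `1e-6` are averaged away;
#' larger ones, ragged rows, non-numeric fields and lower-triangle-only
#' PHYLIP files are parse errors naming the offending line.
#'
#' @param path File path, or a character vector of lines.
#' @param dialect `"native"` or `"phylip"`.
#' @return A `cam_dist` matrix.
#' @export
read_cam_matrix <- function(path, dialect = c("native", "phylip")) {
  dialect <- match.arg(dialect)
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  lines <- lines[nzchar(trimws(lines))]
  parse_error <- function(line_no, why) {
    abort(sprintf("Matrix parse error at line %d: %s", line_no, why),
          class = "camphy_parse_error")
  }
  if (dialect == "native") {
    header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    labels <- header[-1]
    n <- length(labels)
    if (length(lines) != n + 1L) {
      parse_error(length(lines), sprintf("expected %d data rows", n))
    }
    body <- lines[-1]
    first_col <- 2L
  } else {
    n <- suppressWarnings(as.integer(trimws(lines[1])))
    if (is.na(n)) parse_error(1L, "missing species count")
    if (length(lines) != n + 1L) {
      parse_error(length(lines),
                  sprintf("species count is %d but %d rows follow",
                          n, length(lines) - 1L))
    }
    body <- lines[-1]
    labels <- character(n)
    first_col <- 2L
  }
  m <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    fields <- strsplit(trimws(body[i]), "[\t ]+")[[1]]
    if (dialect == "phylip") labels[i] <- fields[1]
    vals <- suppressWarnings(as.numeric(fields[-seq_len(first_col - 1L)]))
    if (length(vals) < n && length(vals) == i - 1L) {
      parse_error(i + 1L, "lower-triangle-only matrices are not supported")
    }
    if (length(vals) != n) {
      parse_error(i + 1L, sprintf("expected %d distances, found %d",
                                  n, length(vals)))
    }
    if (anyNA(vals)) parse_error(i + 1L, "non-numeric distance field")
    m[i, ] <- vals
  }
  if (dialect == "native" && any(vapply(
    seq_len(n), function(i) strsplit(body[i], "\t")[[1]][1] != labels[i],
    logical(1)))) {
    parse_error(2L, "row labels disagree with header labels")
  }
  asym <- max(abs(m - t(m)))
  if (asym > 1e-6) {
    parse_error(1L, sprintf("matrix asymmetric beyond tolerance (%.3g)", asym))
  }
  m <- (m + t(m)) / 2
  diag(m) <- 0
  dimnames(m) <- list(labels, labels)
  class(m) <- c("cam_dist", class(m))
  m
}
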