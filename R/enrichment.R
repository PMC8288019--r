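#' Assign exons to the window containing their midpoint
#'
#' Each exon is counted once, in the complete window containing its midpoint
#' (`(start + end) %/% 2`, half-open convention: a midpoint exactly on a
#' window boundary belongs to the window starting there). Exons on
#' scaffolds without windows, or whose midpoint falls in a dropped terminal
#' remainder, are excluded and counted.
#'
#' @param exons exon intervals (`scaffold`, `start`, `end`, optionally
#'   `name`/`set`).
#' @param windows window table from [window_het_counts()] or
#'   [genome_windows()].
#' @return list of class `exon_assignment`: `assigned` (exon rows plus
#'   `window_key`), `n_assigned`, `n_dropped`.
#' @export
assign_exons <- function(exons, windows) {
  if (any(exons$start >= exons$end))
    stopf("malformed exon interval(s): start >= end")
  if (nrow(windows) == 0) stopf("empty window table")
  wsize <- windows$end[1] - windows$start[1]
  nwin <- vapply(split(windows$start, windows$scaffold), length, 0L)
  mid <- (exons$start + exons$end) %/% 2L
  widx <- mid %/% wsize
  ok <- exons$scaffold %in% names(nwin) &
    widx < nwin[match(exons$scaffold, names(nwin))]
  keys <- window_key(exons$scaffold, widx * wsize)
  assigned <- exons[ok, , drop = FALSE]
  assigned$window_key <- keys[ok]
  rownames(assigned) <- NULL
  structure(list(assigned = assigned, n_assigned = nrow(assigned),
                 n_dropped = sum(!ok)),
            class = "exon_assignment")
}

#' Observed proportion of exons in ROH windows
#'
#' @param assignment an `exon_assignment` from [assign_exons()].
#' @param labeling a `roh_labeling` from [window_roh()], built on the same
#'   window table.
#' @return proportion of assigned exons whose window is ROH-labelled.
#' @export
exon_roh_proportion <- function(assignment, labeling) {
  stopifnot(inherits(assignment, "exon_assignment"),
            inherits(labeling, "roh_labeling"))
  if (assignment$n_assigned == 0) stopf("no exons assigned to windows")
  lab <- window_label_vector(labeling)
  idx <- match(assignment$assigned$window_key, names(lab))
  if (anyNA(idx))
    stopf("assignment and labeling use different window tables")
  mean(lab[idx])
}

window_key <- function(scaffold, start) sprintf("%s:%.0f", scaffold, start)

window_label_vector <- function(labeling) {
  w <- labeling$windows
  stats::setNames(w$roh, window_key(w$scaffold, w$start))
}

#' Permutation test for exon deficiency in ROH
#'
#' Tests whether a gene set's exons fall in ROH windows less often than
#' expected under random placement of the ROH labels. Each replicate
#' shuffles the ROH/non-ROH labels uniformly over the windows — preserving
#' the total number of ROH windows, so the expected proportion equals
#' F_ROH — and recomputes the exon-in-ROH proportion. The shuffling unit is
#' the window: exons clustered in one window move together, which correctly
#' inflates the null variance for clustered gene families. The one-sided
#' deficiency p-value is `(1 + #{replicates <= observed}) / (n_perm + 1)`.
#'
#' @param assignment an `exon_assignment`.
#' @param labeling a `roh_labeling` on the same windows (>= 2 windows).
#' @param n_perm number of label randomizations (default 1000).
#' @param seed integer seed for reproducible shuffles.
#' @return list of class `roh_perm_test`: `observed`, `expected` (= F_ROH),
#'   `p_value`, `null_mean`, `null_sd`, `null` (replicate proportions),
#'   `n_perm`, `n_exons`, `seed`.
#' @export
permute_labels_test <- function(assignment, labeling, n_perm = 1000,
                                seed = NULL) {
  stopifnot(inherits(assignment, "exon_assignment"),
            inherits(labeling, "roh_labeling"))
  if (assignment$n_assigned < 1) stopf("need at least one assigned exon")
  if (labeling$n_windows < 2) stopf("need at least two windows")
  lab <- window_label_vector(labeling)
  idx <- match(assignment$assigned$window_key, names(lab))
  if (anyNA(idx))
    stopf("assignment and labeling use different window tables")
  observed <- mean(lab[idx])
  n_roh <- sum(lab)
  with_seed(seed, {
    null <- vapply(seq_len(n_perm), function(i) {
      perm <- sample(lab)
      stopifnot(sum(perm) == n_roh)  # label count preserved by construction
      mean(perm[idx])
    }, 0)
    structure(list(observed = observed, expected = labeling$F_ROH,
                   p_value = (1 + sum(null <= observed)) / (n_perm + 1),
                   null_mean = mean(null), null_sd = stats::sd(null),
                   null = null, n_perm = n_perm,
                   n_exons = assignment$n_assigned, seed = seed),
              class = "roh_perm_test")
  })
}

#' @export
print.roh_perm_test <- function(x, ...) {
  cat(sprintf(
    "exon-in-ROH deficiency test: observed %.3f vs expected %.3f (n = %d exons)\n  one-sided p = %.4g (%d permutations)\n",
    x$observed, x$expected, x$n_exons, x$p_value, x$n_perm))
  invisible(x)
}
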