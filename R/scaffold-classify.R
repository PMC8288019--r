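#' Sex-classification policy for scaffolds
#'
#' Female:male coverage-ratio bands used to call scaffolds Y-linked
#' (ratio in `[0, 0.04]`) or X-linked (ratio in `[1.5, 2.5]`); everything
#' else is treated as autosomal (the residual class). Both bands are closed
#' intervals. Scaffolds shorter than `min_scaffold_len` are flagged as
#' excluded from downstream analysis.
#'
#' @param y_ratio_range,x_ratio_range numeric length-2 closed intervals.
#' @param min_scaffold_len minimum scaffold length in bp (default 40 kb).
#' @return list of class `sex_class_policy`.
#' @export
sex_class_policy <- function(y_ratio_range = c(0, 0.04),
                             x_ratio_range = c(1.5, 2.5),
                             min_scaffold_len = 40000) {
  stopifnot(length(y_ratio_range) == 2, length(x_ratio_range) == 2,
            y_ratio_range[1] <= y_ratio_range[2],
            x_ratio_range[1] <= x_ratio_range[2])
  if (y_ratio_range[2] >= x_ratio_range[1])
    stopf("Y and X ratio ranges must be disjoint")
  structure(list(y_ratio_range = y_ratio_range,
                 x_ratio_range = x_ratio_range,
                 min_scaffold_len = min_scaffold_len),
            class = "sex_class_policy")
}

#' Female:male coverage ratio per scaffold
#'
#' @param female,male data.frames with `scaffold` and a mean-depth column
#'   (`female_depth`/`male_depth`, or `depth`); both must cover exactly the
#'   same scaffolds. A single data.frame from [simulate_sex_coverage()] can
#'   be passed as `female` with `male` missing.
#' @return data.frame with `scaffold`, `female_depth`, `male_depth`,
#'   `ratio` (plus `length`/`class` columns when present). A male mean depth
#'   of 0 yields an infinite ratio with a warning; such scaffolds fall
#'   outside both bands and classify as autosome.
#' @export
coverage_ratio <- function(female, male = NULL) {
  if (is.null(male) && all(c("female_depth", "male_depth") %in% names(female))) {
    x <- female
  } else {
    fd <- female[[if ("female_depth" %in% names(female)) "female_depth" else "depth"]]
    md <- male[[if ("male_depth" %in% names(male)) "male_depth" else "depth"]]
    only <- c(setdiff(female$scaffold, male$scaffold),
              setdiff(male$scaffold, female$scaffold))
    if (length(only))
      stopf("scaffold(s) present in only one summary: %s",
            paste(only, collapse = ", "))
    m <- match(female$scaffold, male$scaffold)
    x <- female
    x$female_depth <- fd
    x$male_depth <- md[m]
  }
  x$ratio <- ifelse(x$male_depth > 0, x$female_depth / x$male_depth,
                    ifelse(x$female_depth > 0, Inf, 0))
  if (any(x$male_depth == 0 & x$female_depth > 0))
    warnf("%d scaffold(s) with male depth 0: ratio reported as Inf",
          sum(x$male_depth == 0 & x$female_depth > 0))
  x
}

#' Classify scaffolds as autosome / X / Y from coverage ratios
#'
#' @param ratios data.frame from [coverage_ratio()] (needs `scaffold` and
#'   `ratio`; `length` enables the exclusion flag).
#' @param policy a [sex_class_policy()].
#' @return the input with `label` (autosome/X/Y) and `excluded` (TRUE when
#'   the scaffold is shorter than the policy minimum) columns added.
#' @export
classify_scaffolds <- function(ratios, policy = sex_class_policy()) {
  stopifnot(inherits(policy, "sex_class_policy"))
  r <- ratios$ratio
  lab <- rep("autosome", length(r))
  lab[r >= policy$y_ratio_range[1] & r <= policy$y_ratio_range[2]] <- "Y"
  lab[r >= policy$x_ratio_range[1] & r <= policy$x_ratio_range[2]] <- "X"
  ratios$label <- lab
  ratios$excluded <- if ("length" %in% names(ratios))
    !(ratios$length > policy$min_scaffold_len) else FALSE
  ratios
}

#' Autosomal scaffold subset above a length threshold
#'
#' @param labels data.frame with `scaffold`, `label` (from
#'   [classify_scaffolds()]).
#' @param scaffolds scaffold table with lengths.
#' @param min_len keep scaffolds strictly longer than this (bp).
#' @return list with `scaffolds` (the retained scaffold table rows) and
#'   `total_length`. Emits a warning (not an error) when empty.
#' @export
autosomal_subset <- function(labels, scaffolds, min_len = 40000) {
  check_scaffold_table(scaffolds)
  keep <- scaffolds$scaffold %in% labels$scaffold[labels$label == "autosome"] &
    scaffolds$length > min_len
  out <- scaffolds[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0) warnf("no autosomal scaffolds longer than %g bp", min_len)
  list(scaffolds = out, total_length = sum(out$length))
}
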