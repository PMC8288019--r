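# Internal helpers shared across modules.

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so simulations are reproducible without clobbering the
# global stream. `seed = NULL` leaves the RNG alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  code
}

# Derive a stream-specific 31-bit sub-seed from a master seed, so that
# independent components (individuals, gene sets, replicates) get
# decorrelated but reproducible streams.
sub_seed <- function(seed, index) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + 7919 * as.double(index)) %% 2147483647)
}

# 0-based half-open data.frame intervals <-> 1-based closed IRanges
as_iranges <- function(start, end) {
  IRanges::IRanges(start = as.integer(start) + 1L, end = as.integer(end))
}

ranges_to_df <- function(ir, scaffold) {
  data.frame(
    scaffold = rep_len(scaffold, length(ir)),
    start = IRanges::start(ir) - 1L,
    end = IRanges::end(ir)
  )
}

empty_intervals <- function() {
  data.frame(scaffold = character(0), start = integer(0), end = integer(0))
}

# Split an interval data.frame into a named list of IRanges keyed by scaffold
split_ranges <- function(df) {
  if (nrow(df) == 0) return(list())
  lapply(split(df, df$scaffold), function(x) as_iranges(x$start, x$end))
}

# Count points (0-based positions) falling inside 0-based half-open intervals,
# per scaffold.
points_in_intervals <- function(points, intervals) {
  if (nrow(points) == 0 || nrow(intervals) == 0) return(0L)
  total <- 0L
  ivl <- split_ranges(intervals)
  for (s in intersect(unique(points$scaffold), names(ivl))) {
    pos <- points$pos[points$scaffold == s]
    pr <- IRanges::IRanges(start = pos + 1L, width = 1L)
    total <- total + sum(IRanges::countOverlaps(pr, ivl[[s]]) > 0L)
  }
  total
}

# plain-text writers must never emit scientific notation for coordinates
without_scipen <- function(code) {
  old <- options(scipen = 15)
  on.exit(options(old))
  code
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

check_scaffold_table <- function(scaffolds) {
  if (!is.data.frame(scaffolds) || !all(c("scaffold", "length") %in% names(scaffolds)))
    stopf("scaffold table needs columns 'scaffold' and 'length'")
  if (any(scaffolds$length <= 0)) stopf("all scaffold lengths must be > 0")
  if (anyDuplicated(scaffolds$scaffold)) stopf("duplicated scaffold names")
  invisible(scaffolds)
}
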