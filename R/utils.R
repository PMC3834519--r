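#' @keywords internal
"_PACKAGE"

# Run code under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-stage sub-seed, kept inside 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) %% 1e6) * 2099 + offset * 7 + 1)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Numbers formatted for on-disk TSVs: 6 significant digits, no sci-notation
# surprises between platforms.
fmt_num <- function(x) formatC(x, digits = 6, format = "g")

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x == as.integer(x) && x >= 0

is_prob <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x > 0 && x <= 1

RELAPSE <- "relapse"
RELAPSE_FREE <- "relapse_free"

# Validate a label vector against a sample-id set; returns the labels
# reordered to `samples`.
check_labels <- function(labels, samples) {
  if (is.null(names(labels))) stopf("labels must be a named vector")
  missing <- setdiff(samples, names(labels))
  if (length(missing) > 0)
    stopf("labels missing for sample(s): %s", paste(missing, collapse = ", "))
  labels <- labels[samples]
  bad <- setdiff(unique(labels), c(RELAPSE, RELAPSE_FREE))
  if (length(bad) > 0)
    stopf("unknown label value(s): %s (expected '%s'/'%s')",
          paste(bad, collapse = ", "), RELAPSE, RELAPSE_FREE)
  labels
}
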