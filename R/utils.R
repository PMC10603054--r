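# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stop with a classed condition
#'
#' All user-facing errors in the package carry a condition class of the form
#' `bindnet_<what>` so callers (and tests) can match them structurally.
#' @noRd
bn_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(paste0("bindnet_", class), "bindnet_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

bn_warn <- function(class, msg, ...) {
  warning(structure(
    class = c(paste0("bindnet_", class), "bindnet_warning", "warning", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

assert_that <- function(ok, class, msg, ...) {
  if (!isTRUE(ok)) bn_stop(class, msg, ...)
  invisible(TRUE)
}

#' Map DNA alphabet to RNA, validate characters
#'
#' T is silently mapped to U; any symbol outside {A,C,G,U} is an error naming
#' the first offending position (no IUPAC ambiguity handling).
#' @noRd
as_rna <- function(seq, what = "sequence") {
  s <- chartr("t", "u", chartr("T", "U", toupper(seq)))
  bad <- regexpr("[^ACGU]", s)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    bn_stop("alphabet", "non-ACGU character '%s' at position %d of %s",
            substr(s[i], bad[i], bad[i]), bad[i], what)
  }
  s
}

RNA_BASES <- c("A", "C", "G", "U")

rna_complement <- function(seq) chartr("ACGU", "UGCA", seq)

rna_revcomp <- function(seq) {
  vapply(strsplit(rna_complement(seq), ""), function(x) paste(rev(x), collapse = ""), "")
}

# deterministic integer sub-seed derived from a master seed; stays < 2^31
derive_seed <- function(seed, salt) {
  (as.numeric(seed) * 48271 + salt * 1009) %% 2147483647
}
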