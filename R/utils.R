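# Internal helpers shared across modules.

# Run `code` under a temporary RNG seed, restoring the caller's RNG state.
# Seeds passed around the package must stay below 2^31 - 1.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a parent seed and a stream index, kept < 2^31.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + 7919 * stream) %% 2147483629L)
}

tcrgd_log <- function(level = c("INFO", "WARN", "DEBUG"), ...) {
  level <- match.arg(level)
  opt <- getOption("tcrgd.verbose", FALSE)
  if (level == "DEBUG" && !isTRUE(opt)) return(invisible(NULL))
  message(sprintf("[tcrgd %s] %s", level, paste0(...)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Strip an IMGT allele suffix: "TRGV7*02" -> "TRGV7". Vectorized.

#' Strip allele suffixes from gene calls
#'
#' Gene calls may carry an IMGT allele designation (e.g. \code{"TRGV7*02"}).
#' Clonotype definitions and usage tables operate at gene level, so the
#' \code{"*NN"} suffix is removed. Calls without a suffix pass through.
#'
#' @param calls character vector of V or J gene calls.
#' @return character vector of allele-stripped gene symbols.
#' @examples
#' strip_allele(c("TRGV7*02", "TRDJ1"))
#' @export
strip_allele <- function(calls) {
  sub("\\*.*$", "", calls)
}

# Locus implied by a V call prefix; NA for unsupported loci.
locus_from_v_call <- function(v_call) {
  locus <- rep(NA_character_, length(v_call))
  locus[startsWith(v_call, "TRGV")] <- "TRG"
  locus[startsWith(v_call, "TRDV")] <- "TRD"
  locus
}

stop_tcrgd <- function(fmt, ..., class = "tcrgd_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}
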