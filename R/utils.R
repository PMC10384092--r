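#' @keywords internal
#' @useDynLib gaitTFS, .registration = TRUE
#' @importFrom Rcpp sourceCpp
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a per-stage seed from a master seed
#'
#' A single master seed fans out to independent per-stage seeds by hashing the
#' stage name, so each pipeline stage (simulation, split, initialisation,
#' training) is reproducible in isolation. The result always fits in a 32-bit
#' signed integer.
#'
#' @param master integer master seed.
#' @param stage character stage label, e.g. `"train"`.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, stage) {
  codes <- utf8ToInt(as.character(stage))
  h <- sum(codes * seq_along(codes)) * 131
  as.integer((abs(as.numeric(master)) * 48271 + h) %% 2147483629)
}

## Row-wise softmax; rows are queries, columns keys.
softmax_rows <- function(S) {
  mx <- apply(S, 1L, max)
  E <- exp(S - mx)          # vector recycles down columns = per-row shift
  E / rowSums(E)
}

## Stop with a shape message when an array does not match the expectation.
check_dim <- function(x, expected, what = "tensor") {
  d <- dim(x) %||% length(x)
  ok <- length(d) == length(expected) &&
    all(is.na(expected) | d == expected)
  if (!ok) {
    stop(sprintf("%s has shape (%s), expected (%s)", what,
                 paste(d, collapse = ","),
                 paste(ifelse(is.na(expected), "*", expected), collapse = ",")),
         call. = FALSE)
  }
  invisible(TRUE)
}

is_wholenumber <- function(x, tol = 1e-8) abs(x - round(x)) < tol
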