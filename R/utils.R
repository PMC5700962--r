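# Internal helpers shared across stages.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_value <- function(...) stop(sprintf(...), call. = FALSE)

assert_that <- function(cond, ...) {
  if (!isTRUE(cond)) stop_value(...)
  invisible(TRUE)
}

#' Derive a per-stage seed from a global seed
#'
#' Expands one user-facing seed into reproducible per-stage seeds so that a
#' stage rerun in isolation draws the same random stream it drew inside the
#' full pipeline. Kept below 2^31 - 1 so the result is a valid R integer.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stage) {
  assert_that(is.numeric(seed) && length(seed) == 1L && is.finite(seed),
              "seed must be a single finite number")
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 48271 + h * 16807) %% 2147483647)
}

# Align a matrix to given row/column names, zero-filling absent rows.
align_matrix <- function(m, genes, samples) {
  out <- matrix(0, length(genes), length(samples),
                dimnames = list(genes, samples))
  g <- intersect(genes, rownames(m))
  s <- intersect(samples, colnames(m))
  if (length(s) < length(samples))
    stop_value("samples missing from matrix: %s",
               paste(utils::head(setdiff(samples, colnames(m)), 5), collapse = ", "))
  out[g, s] <- m[g, s]
  out
}

check_labels <- function(labels, samples = NULL) {
  assert_that(!is.null(names(labels)), "labels must be a named vector")
  lv <- unique(as.character(labels))
  assert_that(all(lv %in% c("resistant", "sensitive")),
              "labels must be 'resistant' or 'sensitive'")
  assert_that(length(lv) == 2L, "both label classes must be non-empty")
  if (!is.null(samples))
    assert_that(all(samples %in% names(labels)),
                "labels missing for some samples")
  invisible(labels)
}
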