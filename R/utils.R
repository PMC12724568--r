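#' @importFrom rlang %||% .data
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
ggplot2::autoplot

#' @export
generics::tidy

#' @export
generics::glance

# Coerce any matrix-like input to a numeric dgCMatrix, dimnames preserved.
as_dgc <- function(m) {
  if (!inherits(m, "Matrix")) {
    m <- Matrix::Matrix(as.matrix(m) * 1, sparse = TRUE)
  }
  m <- methods::as(m, "CsparseMatrix")
  if (!methods::is(m, "dMatrix")) m <- m * 1
  methods::as(methods::as(m, "generalMatrix"), "CsparseMatrix")
}
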