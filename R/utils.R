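#' @importFrom methods is
#' @importFrom stats median density rnorm runif rpois rbinom rgamma rmultinom
#'   rlnorm kruskal.test p.adjust pnorm prcomp cor cutree hclust dist
#'   cophenetic quantile sd setNames coef optimize
#' @importFrom utils head read.delim write.table
NULL

# internal: fail with the caller-facing message if cond is not TRUE
stopifnot_msg <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == floor(x)
}

is_fraction <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}

# internal: run expr under a local RNG state seeded with `seed`,
# restoring the caller's state afterwards
with_seed <- function(seed, expr) {
  stopifnot_msg(is_count(seed) || (is.numeric(seed) && seed == floor(seed)),
                "`seed` must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# internal: Scott-rule Gaussian KDE bandwidth, sd * n^(-1/5)
bw_scott <- function(x) {
  b <- sd(x) * length(x)^(-1 / 5)
  if (!is.finite(b) || b <= 0) stop("cannot derive a bandwidth: zero variance")
  b
}

# internal: dense or sparse matrix -> dgCMatrix
as_sparse <- function(m) {
  if (is.matrix(m)) m <- Matrix::Matrix(m, sparse = TRUE)
  methods::as(methods::as(methods::as(m, "dMatrix"), "generalMatrix"), "CsparseMatrix")
}
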