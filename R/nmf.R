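# Frobenius non-negative matrix factorization by multiplicative updates with
# NNDSVD initialization. Written here because the factorization itself, and
# the programs extracted from it, are the core of the method.

# Nonnegative double SVD initialization (Boutsidis & Gallopoulos). Zeros are
# later replaced with small seeded random values so multiplicative updates
# can escape them.
nndsvd_init <- function(A, k) {
  s <- svd(A, nu = k, nv = k)
  W <- matrix(0, nrow(A), k)
  H <- matrix(0, k, ncol(A))
  W[, 1] <- sqrt(s$d[1]) * abs(s$u[, 1])
  H[1, ] <- sqrt(s$d[1]) * abs(s$v[, 1])
  if (k > 1) {
    for (j in 2:k) {
      u <- s$u[, j]; v <- s$v[, j]
      up <- pmax(u, 0); un <- pmax(-u, 0)
      vp <- pmax(v, 0); vn <- pmax(-v, 0)
      npos <- sqrt(sum(up^2)) * sqrt(sum(vp^2))
      nneg <- sqrt(sum(un^2)) * sqrt(sum(vn^2))
      if (npos >= nneg && npos > 0) {
        W[, j] <- sqrt(s$d[j] * npos) * up / sqrt(sum(up^2))
        H[j, ] <- sqrt(s$d[j] * npos) * vp / sqrt(sum(vp^2))
      } else if (nneg > 0) {
        W[, j] <- sqrt(s$d[j] * nneg) * un / sqrt(sum(un^2))
        H[j, ] <- sqrt(s$d[j] * nneg) * vn / sqrt(sum(vn^2))
      }
    }
  }
  list(W = W, H = H)
}

#' Non-negative matrix factorization of a centered-clipped matrix
#'
#' Factorizes a non-negative genes x cells matrix into `basis` (genes x k) and
#' `loadings` (k x cells) minimizing Frobenius reconstruction error, using
#' multiplicative updates from an NNDSVD start whose zero entries are filled
#' with small seeded random values. Deterministic for a fixed seed.
#'
#' @param x a `centered_nonneg` object or a non-negative numeric matrix with
#'   row (gene) names.
#' @param k factorization rank; must not exceed either matrix dimension.
#' @param seed integer seed for the initialization fill-in.
#' @param max_iter maximum multiplicative-update iterations.
#' @param tol stop when the relative decrease of the reconstruction error
#'   falls below this.
#' @return object of class `nmf_result`: `basis`, `loadings`, `k`, `seed`,
#'   `n_iter`, `rec_error` (Frobenius) and the per-iteration `error_trace`.
#' @export
run_nmf <- function(x, k, seed = 1L, max_iter = 500L, tol = 1e-4) {
  A <- if (inherits(x, "centered_nonneg")) x$values else as.matrix(x)
  if (is.null(rownames(A))) rownames(A) <- sprintf("g%04d", seq_len(nrow(A)))
  if (any(A < 0)) stop("matrix must be non-negative")
  if (k < 1 || k > min(dim(A)))
    stop(sprintf("rank k=%d outside 1..min(genes, cells)=%d", k, min(dim(A))))
  init <- nndsvd_init(A, k)
  W <- init$W; H <- init$H
  with_seed(seed, {
    fill <- mean(A) * 1e-4
    zw <- W <= 0; zh <- H <= 0
    W[zw] <- fill * stats::runif(sum(zw))
    H[zh] <- fill * stats::runif(sum(zh))
  })
  eps <- .Machine$double.eps
  nA <- sqrt(sum(A^2))
  trace <- numeric(0)
  err <- sqrt(sum((A - W %*% H)^2)) / nA
  trace <- err
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    H <- H * (crossprod(W, A) / (crossprod(W, W %*% H) + eps))
    W <- W * (A %*% t(H)) / (W %*% tcrossprod(H) + eps)
    new_err <- sqrt(sum((A - W %*% H)^2)) / nA
    trace <- c(trace, new_err)
    if (err - new_err < tol * max(err, eps)) { err <- new_err; break }
    err <- new_err
  }
  dimnames(W) <- list(rownames(A), sprintf("comp%d", seq_len(k)))
  dimnames(H) <- list(sprintf("comp%d", seq_len(k)), colnames(A))
  structure(list(basis = W, loadings = H, k = as.integer(k),
                 seed = as.integer(seed), n_iter = it,
                 rec_error = err, error_trace = trace),
            class = "nmf_result")
}

#' @export
print.nmf_result <- function(x, ...) {
  cat(sprintf("nmf_result: k=%d, %d genes x %d cells, %d iterations, relative error %.4g\n",
              x$k, nrow(x$basis), ncol(x$loadings), x$n_iter, x$rec_error))
  invisible(x)
}

#' Extract ranked top-gene programs from an NMF result
#'
#' Each factorization component yields one program: the `top_n` genes with the
#' largest basis coefficients, in non-increasing coefficient order, ties
#' broken by gene id ascending. Matrices with fewer than `top_n` genes yield
#' short programs flagged as such.
#'
#' @param result an `nmf_result`.
#' @param top_n number of genes per program (default 50).
#' @param line_id optional sample-line label stored in each program.
#' @return list of `program` objects (`line_id`, `k`, `component`, `genes`,
#'   `coefficients`, `short`).
#' @export
extract_programs <- function(result, top_n = 50L, line_id = "line1") {
  stopifnot(inherits(result, "nmf_result"))
  genes <- rownames(result$basis)
  n <- min(top_n, length(genes))
  lapply(seq_len(result$k), function(j) {
    w <- result$basis[, j]
    ord <- order(-w, genes)[seq_len(n)]
    structure(list(line_id = line_id, k = result$k, component = j,
                   genes = genes[ord], coefficients = unname(w[ord]),
                   short = n < top_n),
              class = "program")
  })
}

#' @export
print.program <- function(x, ...) {
  cat(sprintf("program %s k=%d comp=%d: %d genes (%s, ...)\n", x$line_id, x$k,
              x$component, length(x$genes),
              paste(utils::head(x$genes, 3), collapse = ", ")))
  invisible(x)
}

#' Run NMF across a range of ranks for one sample line
#'
#' Runs one seeded factorization per rank in `ks` and pools the extracted
#' top-gene programs; ranks 6-9 give the canonical 30 programs per line.
#'
#' @param x `centered_nonneg` or non-negative matrix (one line's cells).
#' @param ks integer vector of ranks.
#' @param seed base seed; each rank uses a seed derived from it.
#' @param top_n genes per program.
#' @param line_id label stored in the programs.
#' @inheritParams run_nmf
#' @return a `program_collection`: list of programs named `line_k_component`.
#' @export
run_nmf_range <- function(x, ks = 6:9, seed = 1L, top_n = 50L,
                          line_id = "line1", max_iter = 500L, tol = 1e-4) {
  progs <- list()
  for (k in ks) {
    res <- run_nmf(x, k, seed = derive_seed(seed, paste0(line_id, "_k", k)),
                   max_iter = max_iter, tol = tol)
    progs <- c(progs, extract_programs(res, top_n = top_n, line_id = line_id))
  }
  program_collection(progs)
}

#' Bundle programs into an indexed collection
#'
#' @param programs list of `program` objects with unique
#'   (line, k, component) indices.
#' @return list of class `program_collection`, named `line_k_component`.
#' @export
program_collection <- function(programs) {
  ids <- vapply(programs, function(p)
    sprintf("%s_k%d_c%d", p$line_id, p$k, p$component), "")
  if (anyDuplicated(ids)) stop("duplicate (line, k, component) indices")
  names(programs) <- ids
  structure(programs, class = "program_collection")
}

#' @export
print.program_collection <- function(x, ...) {
  lines <- unique(vapply(x, `[[`, "", "line_id"))
  cat(sprintf("program_collection: %d programs from %d line(s)\n",
              length(x), length(lines)))
  invisible(x)
}

#' @export
`[.program_collection` <- function(x, i) {
  program_collection(unclass(x)[i])
}
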