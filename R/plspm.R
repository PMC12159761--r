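#' Specify a PLS path model
#'
#' Defines the latent blocks, the acyclic inner model and the estimation
#' settings for [fit_plspm()]. The inner model is given as a
#' lower-triangular boolean (or 0/1) matrix in latent order: `paths[j, k]
#' = TRUE` means latent `k` is a predictor of latent `j`.
#'
#' @param blocks named list: latent name -> character vector of manifest
#'   column names.
#' @param paths square lower-triangular logical/numeric matrix with
#'   dimnames equal to `names(blocks)`.
#' @param modes measurement mode per block, `"A"` (reflective, the
#'   default) or `"B"` (formative); recycled if length 1.
#' @param scheme inner weighting scheme: `"path"` (default), `"centroid"`
#'   or `"factorial"`.
#' @param tol convergence tolerance on the maximum outer-weight change.
#' @param max_iterations iteration cap.
#' @return object of class `plspm_spec`.
#' @export
plspm_spec <- function(blocks, paths, modes = "A",
                       scheme = c("path", "centroid", "factorial"),
                       tol = 1e-7, max_iterations = 300L) {
  scheme <- match.arg(scheme)
  if (!is.list(blocks) || is.null(names(blocks)) || any(names(blocks) == ""))
    stop("blocks must be a named list of manifest vectors")
  if (any(!vapply(blocks, length, 1L)))
    stop("every block needs at least one manifest")
  lat <- names(blocks)
  paths <- as.matrix(paths)
  if (!identical(dim(paths), c(length(lat), length(lat))))
    stop("paths must be a ", length(lat), "x", length(lat), " matrix")
  if (is.null(dimnames(paths))) dimnames(paths) <- list(lat, lat)
  if (!identical(rownames(paths), lat) || !identical(colnames(paths), lat))
    stop("paths dimnames must equal names(blocks), in order")
  mode(paths) <- "logical"
  if (any(paths[upper.tri(paths, diag = TRUE)]))
    stop("paths must be strictly lower-triangular in latent order (acyclic)")
  modes <- rep_len(toupper(modes), length(lat))
  if (!all(modes %in% c("A", "B"))) stop("modes must be 'A' or 'B'")
  names(modes) <- lat
  structure(list(blocks = blocks, paths = paths, modes = modes,
                 scheme = scheme, tol = tol,
                 max_iterations = as.integer(max_iterations)),
            class = "plspm_spec")
}

# sample sd with the usual n-1 denominator; scores are standardised to
# unit sample variance throughout
.unit_scale <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("constant latent score (singular block)")
  x / s
}

#' Fit a PLS path model (Lohmöller iteration)
#'
#' Manifests are standardised; outer weights start equal within each
#' block. Each iteration (i) forms inner proxies from the chosen scheme
#' (`path`: regression coefficients on predecessors plus correlations
#' with successors; `centroid`: correlation signs; `factorial`:
#' correlations), (ii) updates outer weights by mode A (correlation with
#' the proxy) or mode B (multiple regression of the proxy on the block),
#' and (iii) rescales scores to unit variance, until the largest
#' outer-weight change falls below `tol`. Path coefficients are then OLS
#' regressions of each endogenous latent on its predecessors, and
#' \eqn{GoF = \sqrt{\overline{communality} \times \overline{R^2}}}.
#' Sign indeterminacy is resolved by forcing each latent score to
#' correlate positively with its first manifest, which makes the fit
#' deterministic and invariant to sample order.
#'
#' @param data data.frame (or matrix) containing every manifest column;
#'   rows with missing values in the manifests are dropped (listwise).
#' @param spec a [plspm_spec()].
#' @return object of class `plspm_model`: list with `scores` (n x
#'   latents, unit variance), `outer_weights`, `loadings`,
#'   `communalities`, `path_coefficients` (matrix, `[j, k]` = effect of
#'   `k` on `j`), `r_squared` (endogenous latents), `gof`, `iterations`,
#'   `n`, `spec`.
#' @export
fit_plspm <- function(data, spec) {
  stopifnot(inherits(spec, "plspm_spec"))
  manifests <- unlist(spec$blocks, use.names = FALSE)
  miss <- setdiff(manifests, colnames(data))
  if (length(miss)) stop("data lacks manifest columns: ", paste(miss, collapse = ", "))
  X <- as.matrix(as.data.frame(data)[, manifests, drop = FALSE])
  if (!is.numeric(X)) stop("manifest columns must be numeric")
  keep <- stats::complete.cases(X)
  X <- X[keep, , drop = FALSE]
  n <- nrow(X)
  if (n < length(manifests) + 2L)
    stop("too few complete rows (", n, ") for ", length(manifests), " manifests")
  if (any(apply(X, 2, stats::sd) == 0))
    stop("constant manifest column(s): ",
         paste(manifests[apply(X, 2, stats::sd) == 0], collapse = ", "))
  X <- scale(X)

  lat <- names(spec$blocks)
  L <- length(lat)
  bidx <- lapply(spec$blocks, function(m) match(m, manifests))
  adj <- spec$paths | t(spec$paths)  # inner connectivity (symmetric)

  w <- lapply(bidx, function(ix) rep(1, length(ix)))
  score_of <- function(wl) {
    Y <- sapply(seq_len(L), function(b)
      .unit_scale(as.vector(X[, bidx[[b]], drop = FALSE] %*% wl[[b]])))
    colnames(Y) <- lat
    Y
  }
  normalise <- function(wl) {
    for (b in seq_len(L)) {
      s <- as.vector(X[, bidx[[b]], drop = FALSE] %*% wl[[b]])
      wl[[b]] <- wl[[b]] / stats::sd(s)
      if (stats::cor(as.vector(X[, bidx[[b]], drop = FALSE] %*% wl[[b]]),
                     X[, bidx[[b]][1]]) < 0)
        wl[[b]] <- -wl[[b]]
    }
    wl
  }
  w <- normalise(w)

  iter <- 0L
  repeat {
    iter <- iter + 1L
    Y <- score_of(w)
    R <- stats::cor(Y)
    E <- matrix(0, L, L, dimnames = list(lat, lat))
    for (j in seq_len(L)) {
      conn <- which(adj[j, ])
      if (!length(conn)) next
      if (spec$scheme == "centroid") {
        E[conn, j] <- sign(R[conn, j])
      } else if (spec$scheme == "factorial") {
        E[conn, j] <- R[conn, j]
      } else {  # path weighting
        preds <- which(spec$paths[j, ])
        succs <- which(spec$paths[, j])
        if (length(preds)) {
          b <- solve(R[preds, preds, drop = FALSE], R[preds, j])
          E[preds, j] <- b
        }
        if (length(succs)) E[succs, j] <- R[succs, j]
      }
    }
    w_new <- w
    for (b in seq_len(L)) {
      if (!any(adj[b, ])) { next }  # isolated latent keeps its weights
      Z <- .unit_scale(as.vector(Y %*% E[, b]))
      Xb <- X[, bidx[[b]], drop = FALSE]
      if (spec$modes[b] == "A") {
        w_new[[b]] <- as.vector(stats::cor(Xb, Z))
      } else {
        w_new[[b]] <- as.vector(solve(crossprod(Xb), crossprod(Xb, Z)))
      }
    }
    w_new <- normalise(w_new)
    delta <- max(abs(unlist(w_new) - unlist(w)))
    w <- w_new
    if (delta < spec$tol) break
    if (iter >= spec$max_iterations)
      stop("PLS-PM did not converge in ", spec$max_iterations, " iterations")
  }

  Y <- score_of(w)
  loadings <- lapply(seq_len(L), function(b)
    as.vector(stats::cor(X[, bidx[[b]], drop = FALSE], Y[, b])))
  names(loadings) <- lat
  communalities <- unlist(lapply(loadings, function(l) l^2))
  names(communalities) <- manifests[unlist(bidx)]

  P <- matrix(0, L, L, dimnames = list(lat, lat))
  r2 <- c()
  for (j in seq_len(L)) {
    preds <- which(spec$paths[j, ])
    if (!length(preds)) next
    fit <- stats::lm.fit(cbind(1, Y[, preds, drop = FALSE]), Y[, j])
    P[j, preds] <- fit$coefficients[-1]
    r2[lat[j]] <- 1 - sum(fit$residuals^2) / sum((Y[, j] - mean(Y[, j]))^2)
  }
  gof_val <- sqrt(mean(communalities) * mean(r2))

  structure(list(scores = Y,
                 outer_weights = w,
                 loadings = loadings,
                 communalities = communalities,
                 path_coefficients = P,
                 r_squared = r2,
                 gof = gof_val,
                 iterations = iter,
                 n = n,
                 spec = spec),
            class = "plspm_model")
}

#' @export
print.plspm_model <- function(x, ...) {
  cat(sprintf("PLS-PM model: %d latents, n = %d, GoF = %.3f (%d iterations)\n",
              ncol(x$scores), x$n, x$gof, x$iterations))
  pc <- x$path_coefficients
  for (j in rownames(pc)) for (k in colnames(pc))
    if (x$spec$paths[j, k])
      cat(sprintf("  %s -> %s: %+.3f\n", k, j, pc[j, k]))
  invisible(x)
}

#' Goodness of fit of a fitted PLS path model
#'
#' \eqn{GoF = \sqrt{\overline{communality} \times \overline{R^2}}} over
#' all manifests and all endogenous latents.
#'
#' @param model a `plspm_model`.
#' @return scalar in `[0, 1]`.
#' @export
gof <- function(model) {
  stopifnot(inherits(model, "plspm_model"))
  sqrt(mean(model$communalities) * mean(model$r_squared))
}

#' Bootstrap confidence intervals for PLS-PM path coefficients
#'
#' Resamples rows with replacement, refits the model, and summarises each
#' structural path's coefficient distribution. Resamples in which a
#' manifest becomes constant (refit impossible) are skipped and counted.
#' A path is flagged significant when its percentile interval excludes 0.
#'
#' @param model fitted `plspm_model` (point estimates).
#' @param data the data used to fit `model`.
#' @param spec the [plspm_spec()] used to fit `model`.
#' @param n_boot bootstrap resamples; 0 returns the estimates with no
#'   intervals or flags.
#' @param seed RNG seed.
#' @param conf confidence level of the percentile interval.
#' @return `data.frame` with one row per path: `from`, `to`, `estimate`,
#'   and (when `n_boot > 0`) `se`, `ci_lower`, `ci_upper`, `significant`;
#'   attribute `n_skipped` counts skipped resamples.
#' @export
bootstrap_paths <- function(model, data, spec, n_boot = 500L, seed = 1L,
                            conf = 0.95) {
  stopifnot(inherits(model, "plspm_model"), inherits(spec, "plspm_spec"))
  idx <- which(spec$paths, arr.ind = TRUE)
  est <- data.frame(from = colnames(spec$paths)[idx[, 2]],
                    to = rownames(spec$paths)[idx[, 1]],
                    estimate = model$path_coefficients[idx],
                    stringsAsFactors = FALSE)
  if (n_boot <= 0) return(est)

  df <- as.data.frame(data)
  n <- model$n
  set.seed(seed)
  draws <- matrix(NA_real_, n_boot, nrow(est))
  skipped <- 0L
  for (b in seq_len(n_boot)) {
    rows <- sample.int(nrow(df), n, replace = TRUE)
    fit_b <- tryCatch(fit_plspm(df[rows, , drop = FALSE], spec),
                      error = function(e) NULL)
    if (is.null(fit_b)) { skipped <- skipped + 1L; next }
    draws[b, ] <- fit_b$path_coefficients[idx]
  }
  ok <- stats::complete.cases(draws)
  if (!any(ok)) stop("all bootstrap refits failed")
  a <- (1 - conf) / 2
  est$se <- apply(draws[ok, , drop = FALSE], 2, stats::sd)
  ci <- apply(draws[ok, , drop = FALSE], 2, stats::quantile, probs = c(a, 1 - a))
  est$ci_lower <- ci[1, ]
  est$ci_upper <- ci[2, ]
  est$significant <- est$ci_lower > 0 | est$ci_upper < 0
  attr(est, "n_skipped") <- skipped
  est
}
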