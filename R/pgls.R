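#' Read and validate a rooted Newick tree
#'
#' Parses a Newick file with branch lengths and validates what the
#' comparative analysis needs: unique tip labels and non-negative branch
#' lengths.
#'
#' @param path Path to a Newick file (or a Newick string).
#' @return An `ape` `phylo` tree.
#' @export
read_newick <- function(path) {
  tr <- tryCatch(
    suppressWarnings(  # ape warns before returning NULL; we raise our own error
      if (file.exists(path)) ape::read.tree(path) else ape::read.tree(text = path)),
    error = function(e) abort(paste("Newick parse error:", conditionMessage(e))))
  if (is.null(tr)) abort("Newick parse error: no tree found")
  if (anyDuplicated(tr$tip.label)) abort("tip labels are not unique")
  if (is.null(tr$edge.length)) abort("tree has no branch lengths")
  if (any(tr$edge.length < 0)) abort("negative branch lengths")
  tr
}

#' Brownian-motion variance-covariance matrix of a tree
#'
#' Under Brownian trait evolution the expected covariance of two tips is
#' the shared root-to-MRCA path length; the variance of a tip is its
#' root-to-tip depth.
#'
#' @param tree A `phylo` tree.
#' @return A symmetric positive semidefinite matrix with tip labels as
#'   dimnames.
#' @export
brownian_vcv <- function(tree) {
  ape::vcv.phylo(tree)
}

#' Pagel's lambda transform of a phylogenetic covariance matrix
#'
#' Multiplies the off-diagonal entries by `lambda`, leaving tip variances
#' unchanged: `lambda = 1` is pure Brownian covariance, `lambda = 0`
#' removes all phylogenetic signal.
#'
#' @param V Covariance matrix.
#' @param lambda Scalar in \[0, 1\].
#' @return Transformed matrix.
#' @export
pagel_transform <- function(V, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda < 0 || lambda > 1) {
    abort("lambda must be a scalar in [0, 1]")
  }
  W <- lambda * V
  diag(W) <- diag(V)
  W
}

# Gaussian log-likelihood of GLS residuals with sigma^2 profiled out
# (ML: sigma2_hat = RSS/n). Returns fit pieces for reuse.
pgls_core <- function(y, X, V) {
  n <- length(y)
  L <- chol(V)  # V = t(L) %*% L
  w_y <- backsolve(L, y, transpose = TRUE)
  w_X <- backsolve(L, X, transpose = TRUE)
  qrW <- qr(w_X)
  if (qrW$rank < ncol(X)) abort("singular design matrix")
  beta <- qr.coef(qrW, w_y)
  res <- w_y - w_X %*% beta
  rss <- sum(res^2)
  logdetV <- 2 * sum(log(diag(L)))
  sigma2_ml <- rss / n
  ll <- -0.5 * (n * log(2 * pi * sigma2_ml) + logdetV + n)
  list(beta = beta, rss = rss, logLik = ll, qrW = qrW, w_y = w_y, w_X = w_X,
       logdetV = logdetV)
}

#' Phylogenetic generalized least squares regression
#'
#' Fits y = X beta + e with e ~ N(0, sigma^2 V(lambda)), where V is the
#' Brownian covariance of the (pruned) tree and V(lambda) applies Pagel's
#' transform. `lambda` is either a fixed value in \[0, 1\] or `"ML"`, in
#' which case it maximizes the profile Gaussian log-likelihood over
#' \[0, 1\] (bounded search, tolerance 1e-6, ties broken toward smaller
#' lambda by comparing the boundary fits). Coefficient standard errors use
#' sigma^2 = RSS / (n - p); a sequential (type-I) ANOVA table is computed
#' in the given term order on the whitened data.
#'
#' Species present in the data but absent from the tree (and vice versa)
#' are pruned with a warning, mirroring how species missing from a
#' published phylogeny are dropped from a comparative analysis.
#'
#' @param data A data frame containing `species` plus the model columns.
#' @param formula Model formula, e.g.
#'   `pupal_h_diff ~ sternite_complexity_diff + scutum_mm_male + scutum_mm_diff`.
#' @param tree A `phylo` tree whose tip labels match `data$species`.
#' @param lambda `"ML"` (default) or a fixed value in \[0, 1\].
#' @param species Name of the species-label column (default `"species"`).
#' @return An object of class `pgls_fit`; see [tidy.pgls_fit()],
#'   [glance.pgls_fit()], [anova.pgls_fit()].
#' @export
pgls <- function(data, formula, tree, lambda = "ML", species = "species") {
  stopifnot(is.data.frame(data), inherits(tree, "phylo"))
  if (!species %in% names(data)) abort(paste("no column", species))
  vars <- all.vars(formula)
  miss_var <- setdiff(vars, names(data))
  if (length(miss_var)) abort(paste("missing model columns:", paste(miss_var, collapse = ", ")))
  d <- data[stats::complete.cases(data[vars]), c(species, vars)]
  common <- intersect(d[[species]], tree$tip.label)
  if (length(common) < length(vars) + 1) {
    abort("too few species shared between data and tree")
  }
  dropped_data <- setdiff(d[[species]], common)
  dropped_tips <- setdiff(tree$tip.label, common)
  if (length(dropped_data)) {
    warn(paste("species not in tree, dropped:", paste(dropped_data, collapse = ", ")))
  }
  tr <- ape::keep.tip(tree, common)
  d <- d[match(tr$tip.label, d[[species]]), ]
  y <- d[[vars[1]]]
  X <- stats::model.matrix(formula, d)
  n <- length(y)
  V <- brownian_vcv(tr)

  fit_at <- function(lam) pgls_core(y, X, pagel_transform(V, lam))
  if (identical(lambda, "ML")) {
    opt <- optimize(function(l) fit_at(l)$logLik, c(0, 1),
                    maximum = TRUE, tol = 1e-6)
    cand <- c(0, opt$maximum, 1)
    lls <- vapply(cand, function(l) fit_at(l)$logLik, numeric(1))
    # ties (within optimizer tolerance) break toward smaller lambda
    lambda_hat <- cand[which(lls >= max(lls) - 1e-8)[1]]
    lambda_mode <- "ML"
  } else {
    if (!is.numeric(lambda) || lambda < 0 || lambda > 1) {
      abort("lambda must be 'ML' or a value in [0, 1]")
    }
    lambda_hat <- lambda
    lambda_mode <- "fixed"
  }
  core <- fit_at(lambda_hat)
  p <- ncol(X)
  df_res <- n - p
  sigma2 <- core$rss / df_res
  XtViX_inv <- chol2inv(qr.R(core$qrW))
  se <- sqrt(sigma2 * diag(XtViX_inv))
  tval <- as.vector(core$beta) / se
  pval <- 2 * pt(abs(tval), df_res, lower.tail = FALSE)

  # sequential ANOVA on the whitened regression
  av <- seq_anova(core$w_y, core$w_X, attr(X, "assign"),
                  attr(stats::terms(formula), "term.labels"), core$rss, df_res)

  structure(
    list(formula = formula, coef = setNames(as.vector(core$beta), colnames(X)),
         se = setNames(se, colnames(X)), t = setNames(tval, colnames(X)),
         p = setNames(pval, colnames(X)),
         lambda = lambda_hat, lambda_mode = lambda_mode,
         sigma2 = sigma2, logLik = core$logLik, n = n, df_residual = df_res,
         rss = core$rss, anova = av, species = tr$tip.label, tree = tr,
         dropped = list(data = dropped_data, tips = dropped_tips)),
    class = "pgls_fit")
}

# sequential (type-I) sums of squares by successive orthogonal projection
# of the whitened response on the growing design
seq_anova <- function(w_y, w_X, assign, term_labels, rss, df_res) {
  terms_idx <- sort(unique(assign[assign > 0]))
  rss_prev <- {
    fit0 <- qr(w_X[, assign == 0, drop = FALSE])
    sum(qr.resid(fit0, w_y)^2)
  }
  if (!length(terms_idx)) {
    return(tibble(term = "Residuals", df = df_res, ss = rss,
                  ms = rss / df_res, statistic = NA_real_, p = NA_real_))
  }
  rows <- purrr::map_dfr(terms_idx, function(k) {
    cols <- which(assign <= k)
    fitk <- qr(w_X[, cols, drop = FALSE])
    rss_k <- sum(qr.resid(fitk, w_y)^2)
    df_k <- sum(assign == k)
    row <- tibble(term = term_labels[k], df = df_k, ss = rss_prev - rss_k)
    rss_prev <<- rss_k
    row
  })
  ms_res <- rss / df_res
  rows |>
    dplyr::mutate(ms = .data$ss / .data$df,
                  statistic = .data$ms / ms_res,
                  p = stats::pf(.data$statistic, .data$df, df_res,
                                lower.tail = FALSE)) |>
    dplyr::bind_rows(tibble(term = "Residuals", df = df_res, ss = rss,
                            ms = ms_res, statistic = NA_real_, p = NA_real_))
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat(sprintf("PGLS fit: %s\n", deparse(x$formula)))
  cat(sprintf("n = %d species, lambda = %.4f (%s), logLik = %.3f\n",
              x$n, x$lambda, x$lambda_mode, x$logLik))
  print(as.data.frame(tidy(x)), digits = 4)
  invisible(x)
}

#' Tidy a PGLS fit
#'
#' @param x A `pgls_fit`.
#' @param ... Unused.
#' @return A tibble with one row per coefficient: `term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`.
#' @method tidy pgls_fit
#' @export
tidy.pgls_fit <- function(x, ...) {
  tibble(term = names(x$coef), estimate = unname(x$coef),
         std.error = unname(x$se), statistic = unname(x$t),
         p.value = unname(x$p))
}

#' Glance at a PGLS fit
#'
#' @param x A `pgls_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `n`, `lambda`, `lambda_mode`, `sigma2`,
#'   `logLik`, `df.residual`.
#' @method glance pgls_fit
#' @export
glance.pgls_fit <- function(x, ...) {
  tibble(n = x$n, lambda = x$lambda, lambda_mode = x$lambda_mode,
         sigma2 = x$sigma2, logLik = x$logLik, df.residual = x$df_residual)
}

#' Sequential ANOVA table of a PGLS fit
#'
#' Type-I (sequential) sums of squares in the order terms appear in the
#' model formula, on the whitened (phylogenetically decorrelated) scale.
#'
#' @param object A `pgls_fit`.
#' @param ... Unused.
#' @return A tibble: `term`, `df`, `ss`, `ms`, `statistic`, `p`.
#' @method anova pgls_fit
#' @export
anova.pgls_fit <- function(object, ...) {
  object$anova
}

#' Profile the lambda log-likelihood
#'
#' Evaluates the profile Gaussian log-likelihood of the PGLS model on a
#' grid of lambda values; the reported maximum is the grid maximum (first
#' one, so ties break toward smaller lambda).
#'
#' @inheritParams pgls
#' @param grid Numeric vector of lambda values in \[0, 1\].
#' @return A tibble `lambda`, `logLik` with attribute `lambda_hat`.
#' @export
lambda_profile <- function(data, formula, tree, grid = seq(0, 1, by = 0.05),
                           species = "species") {
  lls <- vapply(grid, function(l) {
    f <- pgls(data, formula, tree, lambda = l, species = species)
    f$logLik
  }, numeric(1))
  out <- tibble(lambda = grid, logLik = lls)
  attr(out, "lambda_hat") <- grid[which.max(lls)]
  out
}
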