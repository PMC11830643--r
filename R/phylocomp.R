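#' Phylogenetic comparative statistics
#'
#' Shared ancestry induces covariance among tip traits: under Brownian
#' motion the expected covariance of two tips is proportional to the depth
#' of their most recent common ancestor. The functions here derive that
#' covariance matrix from a tree, measure phylogenetic signal (Blomberg's
#' K, Pagel's lambda), and fit phylogenetically corrected linear models
#' whose ANOVA statistics are tested by residual randomization in a
#' permutation procedure (RRPP).
#'
#' @name phylocomp
#' @keywords internal
NULL

#' Read a phylogeny from Newick or NEXUS
#'
#' Branch lengths (in Myr) are required; negative branch lengths and
#' duplicated tip labels are rejected.
#'
#' @param path tree file; `.nex`/`.nexus` is read as NEXUS, anything else
#'   as Newick.
#' @return an [ape::read.tree()] `phylo` object.
#' @export
read_phylogeny <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  tree <- if (ext %in% c("nex", "nexus")) {
    ape::read.nexus(path)
  } else {
    ape::read.tree(path)
  }
  if (inherits(tree, "multiPhylo")) tree <- tree[[1L]]
  check_phylogeny(tree)
  tree
}

check_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("tree has negative branch lengths")
  if (anyDuplicated(tree$tip.label)) stop("tip labels are not unique")
  invisible(tree)
}

#' Phylogenetic variance-covariance matrix
#'
#' Entry (i, j) is the depth (shared root-to-MRCA path length) of tips i
#' and j; the diagonal holds root-to-tip distances. Pagel's lambda scales
#' the off-diagonal entries: lambda = 0 gives a diagonal (star) matrix,
#' lambda = 1 the untransformed Brownian structure.
#'
#' Computed by accumulating each edge's length over the tip pairs that
#' share it, independently of [ape::vcv.phylo()].
#'
#' @param tree a `phylo` object with branch lengths.
#' @param lambda off-diagonal multiplier in `[0, 1]`.
#' @return an n x n matrix with tip-label dimnames and attribute `lambda`.
#' @export
phylo_vcv <- function(tree, lambda = 1) {
  check_phylogeny(tree)
  stopifnot(lambda >= 0)
  n <- length(tree$tip.label)
  tr <- ape::reorder.phylo(tree, "postorder")
  desc <- vector("list", n + tr$Nnode)
  for (i in seq_len(n)) desc[[i]] <- i
  C <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (k in seq_len(nrow(tr$edge))) {
    child <- tr$edge[k, 2L]
    tips <- desc[[child]]
    C[tips, tips] <- C[tips, tips] + tr$edge.length[k]
    parent <- tr$edge[k, 1L]
    desc[[parent]] <- c(desc[[parent]], tips)
  }
  if (lambda != 1) {
    d <- diag(C)
    C <- C * lambda
    diag(C) <- d
  }
  attr(C, "lambda") <- lambda
  C
}

# inverse square root of a covariance matrix via eigendecomposition with an
# eigenvalue floor (near-ultrametric trees give ill-conditioned C)
cov_inv_sqrt <- function(C, floor_frac = 1e-10) {
  eg <- eigen(C, symmetric = TRUE)
  d <- pmax(eg$values, floor_frac * max(eg$values))
  eg$vectors %*% (t(eg$vectors) / sqrt(d))
}

align_trait <- function(trait, tree) {
  if (is.null(names(trait))) {
    if (length(trait) != length(tree$tip.label)) {
      stop("unnamed trait vector length differs from number of tips")
    }
    names(trait) <- tree$tip.label
    return(trait)
  }
  missing <- setdiff(tree$tip.label, names(trait))
  if (length(missing)) {
    stop("trait values missing for tips: ", paste(missing, collapse = ", "))
  }
  trait[tree$tip.label]
}

#' Blomberg's K
#'
#' Ratio of the observed mean squared error of tip values around the
#' phylogenetic mean (using raw deviations) to the mean squared error
#' standardized by the phylogenetic covariance, scaled by the expectation
#' of that ratio under Brownian motion on the given tree, so that K = 1 is
#' the Brownian expectation, K < 1 means less signal than Brownian and
#' K > 1 more. Significance is assessed by shuffling trait values across
#' tips: p = (count of permuted K >= observed + 1) / (n_perm + 1).
#'
#' @param trait named numeric vector (names = tip labels) or unnamed vector
#'   in tip order.
#' @param tree a `phylo` object.
#' @param n_perm number of tip shuffles (0 skips the test).
#' @param seed integer seed for the permutations.
#' @return list with elements `K`, `p`, `n_perm`.
#' @export
blomberg_K <- function(trait, tree, n_perm = 999L, seed = NULL) {
  y <- align_trait(trait, tree)
  if (stats::var(y) == 0) stop("trait is constant: signal undefined")
  C <- phylo_vcv(tree)
  n <- length(y)
  Cinv <- solve(C)
  sum_cinv <- sum(Cinv)
  k_ratio <- function(y) {
    a <- sum(Cinv %*% y) / sum_cinv
    d <- y - a
    mse0 <- sum(d * d) / (n - 1)
    mse <- drop(crossprod(d, Cinv %*% d)) / (n - 1)
    mse0 / mse
  }
  expected <- (sum(diag(C)) - n / sum_cinv) / (n - 1)
  K_obs <- k_ratio(y) / expected
  p <- NA_real_
  if (n_perm > 0L) {
    if (!is.null(seed)) set.seed(seed)
    K_perm <- vapply(seq_len(n_perm),
                     function(i) k_ratio(sample(y)) / expected,
                     numeric(1L))
    p <- (sum(K_perm >= K_obs) + 1) / (n_perm + 1)
  }
  list(K = K_obs, p = p, n_perm = n_perm)
}

#' Pagel's lambda (maximum likelihood)
#'
#' Finds the lambda in `[0, lambda_max]` maximising the multivariate
#' normal log-likelihood of the trait with covariance sigma^2 * C(lambda),
#' profiling out the phylogenetic mean and sigma^2 analytically. A
#' likelihood-ratio test against lambda = 0 (star phylogeny) gives the
#' p-value (chi-squared, 1 df).
#'
#' @inheritParams blomberg_K
#' @param lambda_max upper bound of the search; both `C` and the diagonal
#'   matrix are positive definite, so any value in `[0, 1]` keeps
#'   C(lambda) valid. If the likelihood is not computable at the requested
#'   bound the bound is shrunk with a warning.
#' @return list with elements `lambda`, `sigma2`, `loglik`, `loglik0`, `p`.
#' @export
pagel_lambda <- function(trait, tree, lambda_max = 1) {
  y <- align_trait(trait, tree)
  C <- phylo_vcv(tree)
  n <- length(y)
  d0 <- diag(C)
  loglik_at <- function(lam) {
    Cl <- C * lam
    diag(Cl) <- d0
    ch <- tryCatch(chol(Cl), error = function(e) NULL)
    if (is.null(ch)) return(NA_real_)
    logdet <- 2 * sum(log(diag(ch)))
    Cinv <- chol2inv(ch)
    mu <- sum(Cinv %*% y) / sum(Cinv)
    r <- y - mu
    s2 <- drop(crossprod(r, Cinv %*% r)) / n
    list(ll = -0.5 * (n * log(2 * pi * s2) + logdet + n), s2 = s2)
  }
  while (lambda_max > 1e-6 &&
         (is.na(ll_at_max <- tryCatch(loglik_at(lambda_max)$ll,
                                      error = function(e) NA_real_)))) {
    lambda_max <- lambda_max * 0.95
    warning("covariance singular at requested lambda; shrinking bound to ",
            signif(lambda_max, 4))
  }
  obj <- function(lam) {
    v <- loglik_at(lam)
    if (is.na(v[[1L]])) -Inf else v$ll
  }
  opt <- stats::optimize(obj, c(0, lambda_max), maximum = TRUE, tol = 1e-6)
  # optimize can miss a boundary optimum; check both ends
  cand <- c(opt$maximum, 0, lambda_max)
  lls <- vapply(cand, obj, numeric(1L))
  best <- which.max(lls)
  lam_hat <- cand[best]
  fit <- loglik_at(lam_hat)
  ll0 <- obj(0)
  lr <- max(0, 2 * (fit$ll - ll0))
  list(lambda = lam_hat, sigma2 = fit$s2, loglik = fit$ll, loglik0 = ll0,
       p = stats::pchisq(lr, df = 1L, lower.tail = FALSE))
}

#' Phylogenetic GLS linear model with permutation ANOVA (RRPP)
#'
#' Fits a linear model by generalized least squares — both sides are
#' premultiplied by the inverse square root of the phylogenetic covariance
#' — and evaluates each term of the ordered model sequence with sequential
#' (type I) sums of squares. Significance comes from residual
#' randomization: for each term, the residuals of the reduced model
#' containing all preceding terms are permuted, added back to the reduced
#' fit, and the term's F statistic recomputed; the p-value is the tail
#' probability of the observed F in that distribution (observed included,
#' so the minimum p is 1/(n_perm + 1)). The effect size Z is the standard
#' deviate of log F within the permutation distribution.
#'
#' @param formula model formula, e.g. `pSV ~ substratum + logSL + XS + family`.
#'   Term order matters (sequential SS).
#' @param data data.frame of tip-level observations; if `phy` or `cov` is
#'   supplied, rows are matched to tips via the `taxon` column (or row
#'   names if absent).
#' @param phy optional `phylo` object; its Brownian covariance is used.
#' @param cov optional covariance matrix (overrides `phy`); `NULL` with no
#'   `phy` means ordinary (identity-covariance) ANOVA.
#' @param n_perm number of residual randomizations (default 999).
#' @param seed integer seed.
#' @return a data.frame of class `anova_rrpp` with one row per term plus
#'   `Residuals` and `Total`, columns `Df`, `SS`, `MS`, `Rsq`, `F`, `Z`,
#'   `p`, and attributes `n_perm` and `seed`.
#' @export
pgls_rrpp <- function(formula, data, phy = NULL, cov = NULL,
                      n_perm = 999L, seed = NULL) {
  if (n_perm < 99L) warning("fewer than 99 permutations: p-values are crude")
  if (is.null(cov) && !is.null(phy)) {
    check_phylogeny(phy)
    cov <- phylo_vcv(phy)
  }
  if (!is.null(cov)) {
    labels <- if ("taxon" %in% names(data)) data$taxon else rownames(data)
    missing <- setdiff(rownames(cov), labels)
    extra <- setdiff(labels, rownames(cov))
    if (length(missing) || length(extra)) {
      stop("taxa and covariance tips do not match.\n",
           if (length(missing)) paste0("  tips without data: ",
                                       paste(missing, collapse = ", "), "\n"),
           if (length(extra)) paste0("  data without tips: ",
                                     paste(extra, collapse = ", ")))
    }
    data <- data[match(rownames(cov), labels), , drop = FALSE]
  }
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  trm <- stats::terms(mf)
  term_labels <- attr(trm, "term.labels")
  X <- stats::model.matrix(trm, mf)
  asgn <- attr(X, "assign")
  n <- length(y)
  K <- length(term_labels)

  if (!is.null(cov)) {
    E <- cov_inv_sqrt(cov)
    yt <- drop(E %*% y)
    Xt <- E %*% X
  } else {
    yt <- y
    Xt <- X
  }

  # nested QR decompositions, model 0 (intercept only) .. model K (full);
  # df per term = rank gained, so partial aliasing (e.g. a family level
  # wholly determined by preceding substratum levels) costs df rather than
  # aborting, but a term adding no estimable columns at all is an error
  qrs <- vector("list", K + 1L)
  ranks <- integer(K + 1L)
  for (k in 0:K) {
    Xk <- Xt[, asgn <= k, drop = FALSE]
    qk <- qr(Xk)
    qrs[[k + 1L]] <- qk
    ranks[k + 1L] <- qk$rank
  }
  df_term <- diff(ranks)
  if (any(df_term == 0L)) {
    stop("aliased term: '", term_labels[which(df_term == 0L)[1L]],
         "' adds no estimable columns (rank deficiency)")
  }
  df_res <- n - ranks[K + 1L]
  if (df_res <= 0L) stop("no residual degrees of freedom")

  rss <- function(qr_obj, Y) {
    r <- qr.resid(qr_obj, Y)
    if (is.matrix(r)) colSums(r * r) else sum(r * r)
  }
  rss_obs <- vapply(qrs, rss, numeric(1L), Y = yt)
  ss_term <- -diff(rss_obs)
  ss_total <- rss_obs[1L]
  ss_res <- rss_obs[K + 1L]
  ms_term <- ss_term / df_term
  ms_res <- ss_res / df_res
  f_obs <- ms_term / ms_res

  p_val <- z_val <- rep(NA_real_, K)
  if (n_perm > 0L && K > 0L) {
    if (!is.null(seed)) set.seed(seed)
    perm_idx <- replicate(n_perm, sample.int(n))
    for (k in seq_len(K)) {
      fit_red <- qr.fitted(qrs[[k]], yt)
      res_red <- qr.resid(qrs[[k]], yt)
      Ystar <- fit_red + matrix(res_red[perm_idx], n, n_perm)
      ss_k <- rss(qrs[[k]], Ystar) - rss(qrs[[k + 1L]], Ystar)
      rss_full <- rss(qrs[[K + 1L]], Ystar)
      f_star <- (ss_k / df_term[k]) / (rss_full / df_res)
      p_val[k] <- (sum(f_star >= f_obs[k]) + 1) / (n_perm + 1)
      logf <- log(pmax(c(f_obs[k], f_star), .Machine$double.xmin))
      z_val[k] <- (logf[1L] - mean(logf)) / stats::sd(logf)
    }
  }

  out <- data.frame(
    Df = c(df_term, df_res, n - 1L),
    SS = c(ss_term, ss_res, ss_total),
    MS = c(ms_term, ms_res, NA_real_),
    Rsq = c(ss_term / ss_total, ss_res / ss_total, NA_real_),
    F = c(f_obs, NA_real_, NA_real_),
    Z = c(z_val, NA_real_, NA_real_),
    p = c(p_val, NA_real_, NA_real_),
    row.names = c(term_labels, "Residuals", "Total")
  )
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  attr(out, "formula") <- formula
  class(out) <- c("anova_rrpp", "data.frame")
  out
}

#' @export
print.anova_rrpp <- function(x, digits = 4L, ...) {
  cat("Permutation ANOVA (residual randomization), sequential SS\n")
  f <- attr(x, "formula")
  if (!is.null(f)) cat("Model:", deparse(f), "\n")
  cat("Permutations:", attr(x, "n_perm"), "\n\n")
  df <- as.data.frame(x)
  stars <- ifelse(is.na(df$p), "",
                  ifelse(df$p <= 0.001, "***",
                         ifelse(df$p <= 0.01, "**",
                                ifelse(df$p <= 0.05, "*", ""))))
  df <- cbind(format(round(df, digits)), Sig = stars)
  df[df == "NA"] <- ""
  print(df)
  invisible(x)
}

#' Pearson product-moment correlation
#'
#' @param x,y finite, nonconstant numeric vectors of equal length >= 3.
#' @return correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("inputs must be finite")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("undefined correlation: constant input")
  }
  stats::cor(x, y)
}

#' Pairwise Pearson correlations among trait columns
#'
#' @param records trait table.
#' @param variables columns to correlate (default `pSV`, `logSL`, `XS`).
#' @return symmetric correlation matrix.
#' @export
pearson_matrix <- function(records, variables = c("pSV", "logSL", "XS")) {
  m <- diag(length(variables))
  dimnames(m) <- list(variables, variables)
  for (i in seq_along(variables)) {
    for (j in seq_along(variables)) {
      if (i < j) {
        m[i, j] <- m[j, i] <- pearson_r(records[[variables[i]]],
                                        records[[variables[j]]])
      }
    }
  }
  m
}
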