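#' Canonical correlation analysis with Wilks' Lambda tests
#'
#' Pairs two variable blocks (here the six NPQ relaxation parameters against
#' the daily environmental covariates, conventionally excluding the morning
#' air temperature for collinearity) and extracts canonical variate pairs of
#' maximal correlation. Both blocks are centred and scaled; the canonical
#' structure is computed from the singular value decomposition of the
#' whitened cross-covariance `Sxx^{-1/2} Sxy Syy^{-1/2}`. Significance of
#' each axis is assessed with Wilks' Lambda and Rao's F approximation.
#'
#' @param x,y numeric matrices / data frames with matching rows
#'   (observations) -- the two variable blocks. Requires
#'   `nrow > ncol(x) + ncol(y)`.
#' @param groups,days optional per-row labels; when given, per-group-per-day
#'   centroids of the x-block scores are returned for ordination plots.
#' @return a `cca_result`: `cor` (canonical correlations, non-increasing in
#'   `[0,1]`), `xcoef`/`ycoef` (canonical weights on the scaled variables),
#'   `xscores`/`yscores`, `xloadings`/`yloadings` (correlations of the
#'   original variables with the canonical variates), `wilks` (per-axis
#'   Lambda, F, dfs and p), and optionally `centroids`.
#' @export
run_cca <- function(x, y, groups = NULL, days = NULL) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (nrow(x) != nrow(y)) stop("x and y must have matching rows")
  n <- nrow(x)
  drop0 <- function(m, nm) {
    sds <- apply(m, 2, stats::sd)
    if (any(sds == 0)) {
      warning("dropping zero-variance ", nm, " column(s): ",
              paste(colnames(m)[sds == 0], collapse = ", "))
      m <- m[, sds > 0, drop = FALSE]
    }
    m
  }
  x <- drop0(x, "x"); y <- drop0(y, "y")
  p <- ncol(x); q <- ncol(y)
  if (n <= p + q) stop("need more observations than total variables")
  xs <- scale(x); ys <- scale(y)
  inv_sqrt <- function(S) {
    e <- eigen(S, symmetric = TRUE)
    keep <- e$values > max(e$values) * 1e-12
    if (!all(keep)) warning("rank-deficient block; dropping ", sum(!keep), " dimension(s)")
    e$vectors[, keep, drop = FALSE] %*%
      diag(1 / sqrt(e$values[keep]), sum(keep)) %*%
      t(e$vectors[, keep, drop = FALSE])
  }
  Sxx <- stats::cov(xs); Syy <- stats::cov(ys); Sxy <- stats::cov(xs, ys)
  K <- inv_sqrt(Sxx) %*% Sxy %*% inv_sqrt(Syy)
  sv <- svd(K)
  m <- min(p, q)
  r <- pmin(pmax(sv$d[seq_len(m)], 0), 1)
  xcoef <- inv_sqrt(Sxx) %*% sv$u[, seq_len(m), drop = FALSE]
  ycoef <- inv_sqrt(Syy) %*% sv$v[, seq_len(m), drop = FALSE]
  xsc <- xs %*% xcoef; ysc <- ys %*% ycoef
  dimnames(xcoef) <- list(colnames(x), paste0("CC", seq_len(m)))
  dimnames(ycoef) <- list(colnames(y), paste0("CC", seq_len(m)))
  colnames(xsc) <- colnames(ysc) <- paste0("CC", seq_len(m))
  res <- list(cor = r, xcoef = xcoef, ycoef = ycoef,
              xscores = xsc, yscores = ysc,
              xloadings = stats::cor(xs, xsc), yloadings = stats::cor(ys, ysc),
              wilks = wilks_lambda(r, n, p, q))
  if (!is.null(groups) && !is.null(days)) {
    key <- interaction(groups, days, drop = TRUE)
    cen <- do.call(rbind, lapply(split(seq_len(n), key), function(i) {
      data.frame(group = groups[i][1], day = days[i][1],
                 CC1 = mean(xsc[i, 1]), CC2 = mean(xsc[i, min(2, m)]))
    }))
    rownames(cen) <- NULL
    res$centroids <- cen
  }
  structure(res, class = "cca_result")
}

#' Wilks' Lambda sequential tests for canonical correlations
#'
#' For each axis k, `Lambda_k = prod_{i>=k} (1 - r_i^2)` tests whether the
#' k-th and all later canonical correlations vanish, with Rao's F
#' approximation for the reference distribution.
#'
#' @param r canonical correlations.
#' @param n number of observations.
#' @param p,q number of variables in the two blocks.
#' @return data frame: `axis`, `lambda`, `f_value`, `df1`, `df2`, `p_value`.
#' @export
wilks_lambda <- function(r, n, p, q) {
  m <- length(r)
  rows <- lapply(seq_len(m), function(k) {
    lambda <- prod(1 - r[k:m]^2)
    pk <- p - k + 1; qk <- q - k + 1
    mm <- n - 3 / 2 - (pk + qk) / 2
    s <- if (pk^2 + qk^2 - 5 > 0) sqrt((pk^2 * qk^2 - 4) / (pk^2 + qk^2 - 5)) else 1
    df1 <- pk * qk
    df2 <- mm * s - pk * qk / 2 + 1
    l1s <- lambda^(1 / s)
    fval <- (1 - l1s) / l1s * df2 / df1
    data.frame(axis = k, lambda = lambda, f_value = fval, df1 = df1, df2 = df2,
               p_value = stats::pf(fval, df1, df2, lower.tail = FALSE))
  })
  do.call(rbind, rows)
}

#' Per-day principal component analysis of the kinetic parameters
#'
#' PCA (centred and scaled) of one sampling day's plot-level rows, with
#' genotype-mean coordinates, outlier labelling of genotypes whose mean
#' score exceeds `|z| > 2.5` on any retained component, and a one-way ANOVA
#' of the panel group on each component.
#'
#' @param pheno plot-level phenotype table with `date`, `genotype`, `group`
#'   and the kinetic parameter columns.
#' @param day the sampling day (`Date` or string).
#' @param parameters parameter columns (default the six kinetic parameters).
#' @param n_pc number of components to retain for labelling/tests
#'   (default 3).
#' @return list: `pca` (the [stats::prcomp]), `explained` (fraction of
#'   variance per PC), `scores`, `genotype_means`, `outliers` (data frame of
#'   `genotype`, `component`, `z`), `group_anova` (per-PC p-value of the
#'   group factor).
#' @export
pca_by_day <- function(pheno, day,
                       parameters = c("a_qe", "a_qm", "a_qi", "tau_qe",
                                      "tau_qm", "max_npq"),
                       n_pc = 3) {
  d <- pheno[pheno$date == as.Date(day), , drop = FALSE]
  if (length(unique(d$genotype)) < 3) stop("fewer than 3 genotypes on ", day)
  pc <- stats::prcomp(as.matrix(d[parameters]), center = TRUE, scale. = TRUE)
  n_pc <- min(n_pc, ncol(pc$x))
  scores <- as.data.frame(pc$x[, seq_len(n_pc), drop = FALSE])
  scores$genotype <- d$genotype
  scores$group <- d$group
  gm <- do.call(rbind, lapply(split(scores, scores$genotype), function(s) {
    cbind(data.frame(genotype = s$genotype[1], group = s$group[1]),
          t(colMeans(s[seq_len(n_pc)])))
  }))
  rownames(gm) <- NULL
  out_rows <- list()
  for (j in seq_len(n_pc)) {
    z <- as.numeric(scale(gm[[paste0("PC", j)]]))
    hit <- abs(z) > 2.5
    if (any(hit)) {
      out_rows[[length(out_rows) + 1]] <-
        data.frame(genotype = gm$genotype[hit], component = paste0("PC", j),
                   z = z[hit])
    }
  }
  ga <- vapply(seq_len(n_pc), function(j) {
    if (length(unique(scores$group)) < 2) return(NA_real_)
    stats::anova(stats::lm(scores[[paste0("PC", j)]] ~ factor(scores$group)))[["Pr(>F)"]][1]
  }, numeric(1))
  list(pca = pc,
       explained = pc$sdev^2 / sum(pc$sdev^2),
       scores = scores, genotype_means = gm,
       outliers = if (length(out_rows)) do.call(rbind, out_rows) else
         data.frame(genotype = character(), component = character(), z = numeric()),
       group_anova = data.frame(component = paste0("PC", seq_len(n_pc)),
                                p_value = ga))
}
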