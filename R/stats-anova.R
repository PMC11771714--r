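#' Genotype-by-day ANOVA for a kinetic parameter
#'
#' Sequential (type-I) ANOVA of `parameter ~ Day + Genotype + Day:Genotype`
#' on plot-level (replicate-averaged) data, with day and genotype as
#' categorical fixed factors. Day aliases both developmental stage and the
#' environment of the sampling day.
#'
#' @param pheno plot-level phenotype table with columns `date`, `genotype`
#'   and the parameter.
#' @param parameter column name of the response (e.g. `"a_qi"`).
#' @return data frame with one row per term (`Day`, `Genotype`,
#'   `Day:Genotype`, `Residuals`): `df`, `sum_sq`, `f_value`, `p_value`.
#' @export
anova_gxe <- function(pheno, parameter) {
  d <- data.frame(y = pheno[[parameter]],
                  day = factor(format(pheno$date)),
                  genotype = factor(pheno$genotype))
  if (nlevels(d$day) < 2 || nlevels(d$genotype) < 2) {
    stop("need >= 2 levels of both day and genotype")
  }
  fit <- stats::aov(y ~ day + genotype + day:genotype, data = d)
  s <- summary(fit)[[1]]
  out <- data.frame(term = c("Day", "Genotype", "Day:Genotype", "Residuals")[seq_len(nrow(s))],
                    df = s$Df, sum_sq = s[["Sum Sq"]],
                    f_value = s[["F value"]], p_value = s[["Pr(>F)"]])
  if (!"Day:Genotype" %in% out$term || any(out$df == 0)) {
    warning("interaction inestimable (empty cells); reported as NA")
  }
  out
}

#' Stepwise-AIC environmental model for a kinetic parameter
#'
#' Starting from a linear model containing all environmental covariates
#' (centred and scaled), a both-direction stepwise algorithm removes and
#' re-adds covariates one at a time, each step taking the single change with
#' the lowest AIC, until no change improves it. Run per year or on combined
#' years by subsetting `pheno` beforehand.
#'
#' @param pheno phenotype table (plot-level rows) joined with daily
#'   environmental features.
#' @param parameter response column name.
#' @param covariates character vector of environmental covariate columns.
#' @return list with `model` (the selected [stats::lm]), `coefficients`
#'   (standardized, intercept excluded), `selected` (covariate names),
#'   `r_squared`, `aic`.
#' @export
stepwise_env_model <- function(pheno,
                               parameter,
                               covariates = c("morning_Ta", "morning_VPD",
                                              "morning_Fsd", "precip_to_10am",
                                              "Ta_3day", "VPD_3day", "Fsd_3day",
                                              "Precip_3day_sum")) {
  covariates <- intersect(covariates, names(pheno))
  X <- scale(as.matrix(pheno[covariates]))
  keep <- !is.na(attr(X, "scaled:scale")) & attr(X, "scaled:scale") > 0
  X <- X[, keep, drop = FALSE]
  cn <- kappa(cbind(1, X), exact = TRUE)
  if (cn > 1e8) stop("covariate block is numerically collinear (condition number ",
                     format(cn, digits = 3), "); remove redundant covariates")
  d <- data.frame(y = pheno[[parameter]], X)
  full <- stats::lm(y ~ ., data = d)
  sel <- stats::step(full, scope = list(lower = y ~ 1, upper = stats::formula(full)),
                     direction = "both", trace = 0)
  cf <- stats::coef(sel)
  cf <- cf[setdiff(names(cf), "(Intercept)")]
  list(model = sel, coefficients = cf, selected = names(cf),
       r_squared = summary(sel)$r.squared, aic = stats::AIC(sel))
}

#' Correlate genotype means between two datasets
#'
#' Pearson correlation of per-genotype mean parameter values between two
#' tables -- typically the two field seasons, or one season against an
#' external trait such as yield.
#'
#' @param a,b data frames with a `genotype` column and one column per
#'   parameter (genotype means). `b` may carry a single trait column.
#' @param parameters columns of `a` to correlate; defaults to the kinetic
#'   parameters present in both tables (or, if `b` shares none, each
#'   parameter of `a` against `b`'s single trait column).
#' @return data frame: `parameter`, `n`, `r`, `r_squared`, `p_value`.
#' @export
genotype_mean_correlations <- function(a, b, parameters = NULL) {
  all_params <- c("a_qe", "a_qm", "a_qi", "tau_qe", "tau_qm", "max_npq")
  shared <- intersect(intersect(all_params, names(a)), names(b))
  if (is.null(parameters)) {
    parameters <- if (length(shared)) shared else intersect(all_params, names(a))
  }
  m <- merge(a, b, by = "genotype", suffixes = c("_a", "_b"))
  if (nrow(m) < 3) stop("fewer than 3 shared genotypes")
  trait <- setdiff(names(b), c("genotype", all_params))[1]
  rows <- lapply(parameters, function(p) {
    xa <- if (paste0(p, "_a") %in% names(m)) m[[paste0(p, "_a")]] else m[[p]]
    xb <- if (paste0(p, "_b") %in% names(m)) m[[paste0(p, "_b")]] else if (p %in% shared) m[[p]] else m[[trait]]
    ct <- stats::cor.test(xa, xb)
    data.frame(parameter = p, n = nrow(m), r = unname(ct$estimate),
               r_squared = unname(ct$estimate)^2, p_value = ct$p.value)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
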