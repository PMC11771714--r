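#' Default modeling scenarios for the genotype screen
#'
#' The screen requires the full-vs-null AIC comparison to agree across a set
#' of modeling scenarios before a genotype is flagged. The default set
#' crosses the data subsets (each year separately plus both combined, when
#' two years are present) with two fixed-effect structures: a sampling-day
#' factor, or the daily environmental covariates in its place (the
#' covariates are day-level quantities, so they cannot enter alongside a
#' free day factor).
#'
#' @param pheno disk-level phenotype table with a `date` column.
#' @param env_covariates covariate columns used by the `"env"` structure.
#' @return list of scenarios, each a list with `name`, `years` (or `NULL`
#'   for all rows) and `fixed` (`"day"` or `"env"`).
#' @export
default_scenarios <- function(pheno,
                              env_covariates = c("morning_Ta", "morning_VPD",
                                                 "precip_to_10am", "morning_Fsd",
                                                 "Ta_3day", "VPD_3day")) {
  years <- sort(unique(format(as.Date(pheno$date), "%Y")))
  subsets <- if (length(years) > 1) c(as.list(years), list(NULL)) else list(NULL)
  out <- list()
  for (ss in subsets) for (fx in c("day", "env")) {
    out[[length(out) + 1]] <- list(
      name = paste0(if (is.null(ss)) "combined" else ss, "_", fx),
      years = ss, fixed = fx, env_covariates = env_covariates)
  }
  out
}

#' Nested-AIC mixed-model screen of genotypes against the reference line
#'
#' For each genotype g (other than the reference `RC`) and each modeling
#' scenario, fits the full linear mixed-effects model containing all
#' genotype indicators (treatment-coded against RC, plot random intercept,
#' disk level as residual, maximum likelihood) and a null model in which g
#' is merged into the RC baseline. If the full model has the lower AIC in
#' every usable scenario and the sign of g's coefficient agrees across
#' scenarios, the genotype is flagged as consistently different from RC in
#' that parameter.
#'
#' @param pheno disk-level phenotype table: `genotype`, `plot_id`, `date`,
#'   the response parameter, and the environmental covariate columns used by
#'   `"env"` scenarios.
#' @param parameter response column name.
#' @param scenarios list of scenarios (see [default_scenarios()]).
#' @param reference reference genotype label (default `"RC"`).
#' @param min_usable minimum number of usable (non-singular) scenarios a
#'   genotype must have to be flaggable; defaults to all of them.
#' @param genotypes genotypes to screen (default: all non-reference
#'   genotypes present). Narrowing this skips the null-model fits of the
#'   other genotypes, which all still inform the full model.
#' @return list with `summary` (per genotype: `delta_aic_max` = worst
#'   `AIC(full) - AIC(null)` over usable scenarios, `sign`, `consistent`)
#'   and `details` (per genotype x scenario).
#' @export
mixed_model_screen <- function(pheno, parameter, scenarios = default_scenarios(pheno),
                               reference = "RC", min_usable = length(scenarios),
                               genotypes = NULL) {
  if (!reference %in% pheno$genotype) stop("reference genotype '", reference,
                                           "' absent from data")
  genos <- setdiff(unique(pheno$genotype), reference)
  if (!is.null(genotypes)) genos <- intersect(genos, genotypes)
  details <- list()
  for (sc in scenarios) {
    d <- pheno
    if (!is.null(sc$years)) d <- d[format(as.Date(d$date), "%Y") %in% sc$years, ]
    d$y <- d[[parameter]]
    d$genotype <- stats::relevel(factor(d$genotype), ref = reference)
    d$day <- factor(format(d$date))
    rhs <- if (identical(sc$fixed, "day")) {
      "day"
    } else {
      covs <- intersect(sc$env_covariates, names(d))
      for (cv in covs) d[[cv]] <- as.numeric(scale(d[[cv]]))
      keep <- covs[vapply(covs, function(cv) !anyNA(d[[cv]]) && stats::sd(d[[cv]]) > 0,
                          logical(1))]
      paste(keep, collapse = " + ")
    }
    full_fml <- stats::as.formula(paste("y ~", rhs, "+ genotype + (1 | plot_id)"))
    full <- tryCatch(
      suppressMessages(lme4::lmer(full_fml, data = d, REML = FALSE)),
      error = function(e) NULL)
    usable <- !is.null(full) && !lme4::isSingular(full, tol = 1e-5)
    for (g in genos) {
      if (!usable || !g %in% d$genotype) {
        details[[length(details) + 1]] <- data.frame(
          genotype = g, scenario = sc$name, usable = FALSE,
          delta_aic = NA_real_, sign = NA_real_)
        next
      }
      cf <- lme4::fixef(full)[paste0("genotype", g)]
      dn <- d
      dn$genotype <- factor(ifelse(as.character(dn$genotype) == g, reference,
                                   as.character(dn$genotype)))
      dn$genotype <- stats::relevel(dn$genotype, ref = reference)
      null <- tryCatch(
        suppressMessages(lme4::lmer(full_fml, data = dn, REML = FALSE)),
        error = function(e) NULL)
      ok <- !is.null(null)
      details[[length(details) + 1]] <- data.frame(
        genotype = g, scenario = sc$name, usable = ok,
        delta_aic = if (ok) stats::AIC(full) - stats::AIC(null) else NA_real_,
        sign = sign(unname(cf)))
    }
  }
  details <- do.call(rbind, details)
  summary <- do.call(rbind, lapply(split(details, details$genotype), function(dd) {
    u <- dd[dd$usable, , drop = FALSE]
    flaggable <- nrow(u) >= min_usable
    # AIC ties (|delta| < 1e-6) resolve toward the smaller model
    all_better <- flaggable && all(u$delta_aic < -1e-6)
    sgns <- unique(u$sign)
    sign_ok <- length(sgns) == 1 && sgns != 0
    data.frame(genotype = dd$genotype[1], parameter = parameter,
               n_usable = nrow(u), n_scenarios = nrow(dd),
               delta_aic_max = if (nrow(u)) max(u$delta_aic) else NA_real_,
               sign = if (sign_ok) sgns else 0,
               consistent = all_better && sign_ok)
  }))
  rownames(summary) <- NULL
  list(summary = summary, details = details)
}
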