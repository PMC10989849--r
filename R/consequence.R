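#' Per-sample alpha diversity
#'
#' Richness (count of taxa with abundance > 0) or Shannon entropy
#' (natural log, computed on each sample's relative abundances).
#'
#' @param table an `abundance_table` (counts or relative).
#' @param metric `"richness"` (default) or `"shannon"`.
#' @return named numeric vector over samples.
#' @export
alpha_diversity <- function(table, metric = c("richness", "shannon")) {
  stopifnot(inherits(table, "abundance_table"))
  metric <- match.arg(metric)
  v <- table$values
  if (any(rowSums(v) == 0))
    warning("all-zero sample(s) get alpha diversity 0: ",
            paste(rownames(v)[rowSums(v) == 0], collapse = ", "))
  if (metric == "richness") return(rowSums(v > 0))
  apply(v, 1L, function(x) {
    s <- sum(x)
    if (s == 0) return(0)
    p <- x[x > 0] / s
    -sum(p * log(p))
  })
}

#' Forward-selection ordinary least squares
#'
#' Builds an OLS model for a per-sample response by iteratively adding,
#' from the offered predictors, the one giving the largest adjusted-R^2
#' increase among those whose partial-F entry p-value is below
#' `alpha_enter` and whose adjusted-R^2 gain exceeds `r2_floor`; stops
#' when no candidate qualifies. Near-collinear candidates (condition
#' number of the design above `kappa_max` after entry) are skipped with a
#' warning.
#'
#' @param response numeric per-sample vector.
#' @param predictors data.frame of named numeric per-sample variables,
#'   rows aligned with `response`.
#' @param alpha_enter partial-F entry level, default 0.05.
#' @param r2_floor minimum adjusted-R^2 improvement, default 0.001.
#' @param kappa_max design condition-number guard, default 1e10.
#' @return An object of class `alpha_model`: list with `selected`
#'   (predictor names in entry order), `path` (data.frame step /
#'   variable / adj_r2 / partial_f_p), `fit` (the final `lm`, NULL when
#'   nothing entered), `coefficients` (final coefficient table),
#'   `adj_r2` (final adjusted R^2, 0 for the empty model).
#' @export
forward_select_ols <- function(response, predictors, alpha_enter = 0.05,
                               r2_floor = 0.001, kappa_max = 1e10) {
  predictors <- as.data.frame(predictors)
  if (anyNA(response) || anyNA(predictors)) stop("missing values")
  n <- length(response)
  if (nrow(predictors) != n) stop("response/predictor length mismatch")
  if (n <= ncol(predictors) + 2L)
    stop("need more samples than offered predictors + 2")
  dat <- cbind(data.frame(.y = response), predictors)
  selected <- character()
  path <- data.frame(step = integer(), variable = character(),
                     adj_r2 = numeric(), partial_f_p = numeric(),
                     stringsAsFactors = FALSE)
  adj_now <- 0
  fit_now <- stats::lm(.y ~ 1, data = dat)
  repeat {
    remaining <- setdiff(colnames(predictors), selected)
    if (!length(remaining)) break
    best <- NULL
    for (v in remaining) {
      form <- stats::reformulate(c(selected, v), response = ".y")
      fit <- stats::lm(form, data = dat)
      X <- stats::model.matrix(fit)
      if (kappa(X, exact = TRUE) > kappa_max) {
        warning("skipping near-collinear predictor '", v, "'")
        next
      }
      adj <- summary(fit)$adj.r.squared
      pf <- stats::anova(fit_now, fit)[["Pr(>F)"]][2L]
      if (is.na(pf)) next     # zero residual variance: perfect fit
      if (pf < alpha_enter && adj - adj_now > r2_floor &&
          (is.null(best) || adj > best$adj))
        best <- list(v = v, fit = fit, adj = adj, pf = pf)
    }
    if (is.null(best)) break
    selected <- c(selected, best$v)
    path <- rbind(path, data.frame(step = length(selected),
                                   variable = best$v, adj_r2 = best$adj,
                                   partial_f_p = best$pf,
                                   stringsAsFactors = FALSE))
    fit_now <- best$fit
    adj_now <- best$adj
    if (adj_now > 1 - 1e-12) break        # perfect fit, nothing to add
  }
  coefs <- if (length(selected)) as.data.frame(summary(fit_now)$coefficients)
           else NULL
  structure(list(selected = selected, path = path,
                 fit = if (length(selected)) fit_now else NULL,
                 coefficients = coefs, adj_r2 = adj_now,
                 alpha_enter = alpha_enter),
            class = "alpha_model")
}

#' @export
print.alpha_model <- function(x, ...) {
  if (!length(x$selected)) {
    cat("alpha_model: no predictor entered\n")
  } else {
    cat(sprintf("alpha_model: %s (adjusted R^2 = %.3f)\n",
                paste(x$selected, collapse = " + "), x$adj_r2))
  }
  invisible(x)
}

#' Mantel tests of factors against community turnover
#'
#' Community dissimilarity is Bray-Curtis on relative abundances
#' ([vegan::vegdist()]); each offered factor -- a per-sample numeric
#' vector (converted to an absolute-difference distance) or a precomputed
#' `dist` -- is Mantel-tested against it.
#'
#' @param table an `abundance_table`.
#' @param factors named list of per-sample numeric vectors and/or `dist`
#'   objects covering the table's samples.
#' @param community_metric only `"braycurtis"`.
#' @param method Mantel correlation method, default `"spearman"`.
#' @param n_perm permutations, default 999.
#' @param seed integer; per-factor streams are derived from it.
#' @return data.frame (class `beta_mantel`) with columns `factor`, `r`,
#'   `p_value`.
#' @export
mantel_beta <- function(table, factors, community_metric = "braycurtis",
                        method = c("spearman", "pearson"), n_perm = 999,
                        seed = 1L) {
  stopifnot(inherits(table, "abundance_table"))
  community_metric <- match.arg(community_metric, "braycurtis")
  method <- match.arg(method)
  if (is.null(names(factors)) || any(names(factors) == ""))
    stop("factors must be named")
  rel <- if (table$is_relative) table else to_relative(table)
  comm_d <- vegan::vegdist(rel$values, method = "bray")
  out <- data.frame(factor = names(factors), r = NA_real_,
                    p_value = NA_real_, stringsAsFactors = FALSE)
  for (k in seq_along(factors)) {
    f <- factors[[k]]
    d <- if (inherits(f, "dist")) f else {
      if (length(f) != nrow(rel$values))
        stop("factor '", names(factors)[k], "' length mismatch")
      stats::dist(matrix(f, dimnames = list(rownames(rel$values), NULL)))
    }
    mt <- mantel_test(comm_d, d, method = method, n_perm = n_perm,
                      seed = seed + k)
    out$r[k] <- mt$r
    out$p_value[k] <- mt$p_value
  }
  structure(out, class = c("beta_mantel", "data.frame"))
}
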