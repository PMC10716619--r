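# Nested random-intercept log-linear mixed model:
#   log(y)_ijk = alpha + u_i(city) + u_ij(child in city) + x'beta + e_ijk
# REML point estimation is delegated to lme4; the restricted likelihood is
# re-evaluated in-package through the Woodbury identity so that (a) the
# optimum can be polished to tight tolerance and (b) Satterthwaite
# denominator degrees of freedom can be computed from the variance-parameter
# Hessian without further dependencies.

#' Fit the nested random-intercept determinants model
#'
#' Fits `log(outcome) ~ fixed terms + (1 | city) + (1 | child within city)`
#' by REML. Fixed-effect p values use Wald t statistics with
#' Satterthwaite-type denominator degrees of freedom computed from the
#' curvature of the restricted likelihood in the variance parameters; if that
#' computation fails the normal approximation is used and flagged in
#' `ddf_method`. AIC is reported from a maximum-likelihood refit so screening
#' comparisons across fixed-effect sets are valid.
#'
#' @param data data.frame with columns `city_id`, `child_id`, the outcome and
#'   every fixed term. Determinant factors are releveled to the canonical
#'   references of [determinant_levels()].
#' @param fixed_terms Character vector of fixed-effect column names (possibly
#'   empty for an intercept-only model).
#' @param outcome Name of the strictly positive outcome column (log applied
#'   internally). Default `"pm25_daily_mean"`.
#' @param ddf `"satterthwaite"` (default) or `"normal"`.
#' @param level Confidence level for percent-change intervals.
#' @return Object of class `wearpm_lmm`: list with `alpha`, `betas` (term,
#'   reference, estimate, se, df, p), `percent_changes`, variance components
#'   `sigma2_location`, `sigma2_child`, `sigma2_resid`, `aic` (ML refit),
#'   `ddf_method`, `converged`, `status`, `n`, `n_children`, `n_cities`.
#' @export
fit_lmm <- function(data, fixed_terms = character(),
                    outcome = "pm25_daily_mean",
                    ddf = c("satterthwaite", "normal"), level = 0.95) {
  ddf <- match.arg(ddf)
  dt <- as.data.frame(data)
  need <- c("city_id", "child_id", outcome, fixed_terms)
  miss <- setdiff(need, names(dt))
  if (length(miss)) {
    stop("argument error: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  y0 <- dt[[outcome]]
  if (any(!is.finite(y0)) || any(y0 <= 0)) {
    stop("outcome must be finite and strictly positive before log transform",
         call. = FALSE)
  }
  dt$.y <- log(y0)
  dl <- determinant_levels()
  for (d in intersect(names(dl), fixed_terms)) {
    lv <- intersect(dl[[d]], unique(as.character(dt[[d]])))
    dt[[d]] <- factor(as.character(dt[[d]]), levels = lv)
  }
  rhs <- if (length(fixed_terms)) paste(fixed_terms, collapse = " + ") else "1"
  X <- model.matrix(as.formula(paste("~", rhs)), dt)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    aliased <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("singular design after reference-level coding; aliased column(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  n <- nrow(X); p <- ncol(X)
  dt$.city <- factor(as.character(dt$city_id))
  dt$.child <- factor(paste(dt$city_id, dt$child_id, sep = "//"))

  ref_of <- coef_references(X, fixed_terms, dt)

  if (var(dt$.y) < 1e-12 && p == 1) {
    # degenerate constant outcome, intercept only
    pc <- percent_change(0, 0, Inf, level)
    return(structure(list(
      alpha = mean(dt$.y),
      betas = empty_beta_table(),
      percent_changes = empty_pct_table(),
      sigma2_location = 0, sigma2_child = 0, sigma2_resid = 0,
      aic = NA_real_, ddf_method = "none", converged = TRUE,
      status = "degenerate", n = n,
      n_children = nlevels(dt$.child), n_cities = nlevels(dt$.city)
    ), class = "wearpm_lmm"))
  }

  fml <- as.formula(paste(".y ~", rhs, "+ (1 | .city) + (1 | .child)"))
  msgs <- character()
  fit <- withCallingHandlers(
    lme4::lmer(fml, data = dt, REML = TRUE,
               control = lme4::lmerControl(calc.derivs = FALSE,
                                           check.conv.singular = "ignore")),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w)); invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m)); invokeRestart("muffleMessage")
    }
  )
  converged <- !any(grepl("failed to converge", msgs))

  vc <- as.data.frame(lme4::VarCorr(fit))
  s_city <- sqrt(vc$vcov[match(".city", vc$grp)])
  s_child <- sqrt(vc$vcov[match(".child", vc$grp)])
  s_e <- sqrt(vc$vcov[match("Residual", vc$grp)])
  vp <- c(city = s_city, child = s_child, resid = s_e)

  rml <- make_reml_machine(X, dt$.y, dt$.city, dt$.child)
  vp <- polish_varpar(rml, vp)
  gls <- rml(vp, what = "beta")
  beta <- drop(gls$beta)
  vc_beta <- gls$vcov
  se <- sqrt(diag(vc_beta))

  dfs <- rep(Inf, p)
  ddf_method <- "normal"
  if (ddf == "satterthwaite") {
    sw <- try(satterthwaite_df(rml, vp, p, n), silent = TRUE)
    if (!inherits(sw, "try-error") && all(is.finite(sw))) {
      dfs <- sw
      ddf_method <- "satterthwaite"
    }
  }

  tval <- beta / se
  pval <- 2 * pt(-abs(tval), df = dfs)

  # ML refit for AIC comparability across fixed-effect sets
  aic <- tryCatch(AIC(update_ml(fit)), error = function(e) NA_real_)

  nm <- colnames(X)
  keep <- nm != "(Intercept)"
  betas <- data.table::data.table(
    term = nm[keep],
    reference = ref_of[keep],
    estimate = beta[keep], se = se[keep], df = dfs[keep], p = pval[keep]
  )
  pcs <- if (any(keep)) {
    do.call(rbind, lapply(which(keep), function(j) {
      pc <- percent_change(beta[j], se[j], dfs[j], level)
      data.table::data.table(term = nm[j], pct_change = pc$point,
                             ci_low = pc$ci_low, ci_high = pc$ci_high)
    }))
  } else empty_pct_table()

  structure(list(
    alpha = unname(beta[match("(Intercept)", nm)]),
    betas = betas,
    percent_changes = pcs,
    sigma2_location = unname(vp[1]^2), sigma2_child = unname(vp[2]^2),
    sigma2_resid = unname(vp[3]^2),
    aic = aic, ddf_method = ddf_method, converged = converged,
    status = if (converged) "ok" else "non-convergence flagged",
    n = n, n_children = nlevels(dt$.child), n_cities = nlevels(dt$.city),
    design = X, messages = msgs
  ), class = "wearpm_lmm")
}

#' @export
print.wearpm_lmm <- function(x, ...) {
  cat("Nested random-intercept log-linear model (REML)\n")
  cat(sprintf("  n = %d daily means, %d children, %d cities; ddf: %s; %s\n",
              x$n, x$n_children, x$n_cities, x$ddf_method, x$status))
  cat(sprintf("  variance components (log scale): city %.4f, child %.4f, residual %.4f\n",
              x$sigma2_location, x$sigma2_child, x$sigma2_resid))
  cat(sprintf("  alpha = %.4f   AIC(ML refit) = %.1f\n", x$alpha, x$aic))
  if (nrow(x$betas)) {
    tab <- merge(x$betas, x$percent_changes, by = "term", sort = FALSE)
    print(tab, digits = 4)
  }
  invisible(x)
}

empty_beta_table <- function() {
  data.table::data.table(term = character(), reference = character(),
                         estimate = numeric(), se = numeric(),
                         df = numeric(), p = numeric())
}

empty_pct_table <- function() {
  data.table::data.table(term = character(), pct_change = numeric(),
                         ci_low = numeric(), ci_high = numeric())
}

# reference level (if any) behind each design column
coef_references <- function(X, fixed_terms, dt) {
  asg <- attr(X, "assign")
  labs <- c("(Intercept)", fixed_terms)[asg + 1]
  vapply(seq_len(ncol(X)), function(j) {
    trm <- labs[j]
    if (trm %in% names(dt) && is.factor(dt[[trm]])) levels(dt[[trm]])[1]
    else ""
  }, character(1))
}

update_ml <- function(fit) {
  suppressWarnings(suppressMessages(
    lme4::refitML(fit)
  ))
}

# ---- restricted-likelihood machinery -----------------------------------

# Builds a closure evaluating -2 * restricted log-likelihood (up to an
# additive constant) for variance parameters vp = (sd_city, sd_child, sd_e),
# using the Woodbury identity on the q x q random-effect scale:
#   V = s_e^2 I + Z G Z',  V^-1 = s_e^-2 (I - Z M^-1 Z'),
#   M = Z'Z + s_e^2 G^-1,
#   log|V| = (n - q) log s_e^2 + log|M| + log|G|.
make_reml_machine <- function(X, y, city, child) {
  Zc <- Matrix::t(Matrix::fac2sparse(city))
  Zh <- Matrix::t(Matrix::fac2sparse(child))
  Z <- cbind(Zc, Zh)
  mc <- ncol(Zc); mh <- ncol(Zh)
  ZtZ <- as.matrix(Matrix::crossprod(Z))
  ZtX <- as.matrix(Matrix::crossprod(Z, X))
  Zty <- as.numeric(Matrix::crossprod(Z, y))
  XtX <- crossprod(X); Xty <- drop(crossprod(X, y)); yty <- sum(y * y)
  n <- length(y); p <- ncol(X)

  function(vp, what = "crit") {
    s2 <- pmax(vp, 0)^2
    s2e <- s2[3]
    use <- c(rep(s2[1] > 0, mc), rep(s2[2] > 0, mh))
    if (any(use)) {
      g <- c(rep(s2[1], mc), rep(s2[2], mh))[use]
      q <- sum(use)
      M <- ZtZ[use, use, drop = FALSE]
      diag(M) <- diag(M) + s2e / g
      cM <- chol(M)
      rhs <- cbind(ZtX[use, , drop = FALSE], Zty[use])
      S <- backsolve(cM, forwardsolve(t(cM), rhs))
      ZXu <- ZtX[use, , drop = FALSE]
      XtViX <- (XtX - crossprod(ZXu, S[, seq_len(p), drop = FALSE])) / s2e
      XtViy <- (Xty - drop(crossprod(ZXu, S[, p + 1]))) / s2e
      ytViy <- (yty - sum(Zty[use] * S[, p + 1])) / s2e
      logdetV <- (n - q) * log(s2e) + 2 * sum(log(diag(cM))) + sum(log(g))
    } else {
      XtViX <- XtX / s2e
      XtViy <- Xty / s2e
      ytViy <- yty / s2e
      logdetV <- n * log(s2e)
    }
    XtViX <- (XtViX + t(XtViX)) / 2
    cXVX <- chol(XtViX)
    beta <- backsolve(cXVX, forwardsolve(t(cXVX), XtViy))
    yPy <- ytViy - sum(XtViy * beta)
    crit <- logdetV + 2 * sum(log(diag(cXVX))) + yPy
    if (what == "crit") return(crit)
    list(crit = crit, beta = beta, vcov = chol2inv(cXVX), yPy = yPy)
  }
}

# Tight local polish of the REML optimum in the free (non-zero) variance
# parameters; lme4's optimum is the starting point.
polish_varpar <- function(rml, vp) {
  free <- which(vp > 1e-8 * max(vp[3], 1e-12))
  if (!(3 %in% free)) free <- union(free, 3L)
  par0 <- vp[free]
  obj <- function(par) {
    full <- vp; full[free] <- par
    full[setdiff(1:3, free)] <- 0
    rml(full, "crit")
  }
  opt <- try(optim(par0, obj, method = "L-BFGS-B",
                   lower = rep(1e-10, length(par0)),
                   control = list(factr = 100, pgtol = 1e-12, maxit = 500)),
             silent = TRUE)
  out <- vp
  out[setdiff(1:3, free)] <- 0
  if (!inherits(opt, "try-error") && opt$value <= rml(vp, "crit") + 1e-8) {
    out[free] <- opt$par
  }
  out
}

# Satterthwaite denominator df per fixed-effect coefficient:
#   df_j = 2 v_jj^2 / (g_j' A g_j),
# with v_jj = [vcov(beta)]_jj, g_j its gradient in the variance parameters,
# and A = 2 H^-1 the asymptotic vcov of the variance parameters (H = Hessian
# of the -2 restricted log-likelihood). Finite differences throughout.
satterthwaite_df <- function(rml, vp, p, n) {
  free <- which(vp > 1e-8 * max(vp[3], 1e-12))
  if (!(3 %in% free)) free <- union(free, 3L)
  k <- length(free)
  h <- pmax(vp[free] * 1e-4, 1e-8)
  f_at <- function(delta) {
    full <- vp
    full[free] <- pmax(vp[free] + delta, 1e-12)
    rml(full, "crit")
  }
  H <- matrix(0, k, k)
  f0 <- f_at(rep(0, k))
  for (i in seq_len(k)) {
    ei <- replace(rep(0, k), i, h[i])
    H[i, i] <- (f_at(ei) - 2 * f0 + f_at(-ei)) / h[i]^2
    if (i < k) for (j in (i + 1):k) {
      ej <- replace(rep(0, k), j, h[j])
      H[i, j] <- H[j, i] <-
        (f_at(ei + ej) - f_at(ei - ej) - f_at(-ei + ej) + f_at(-ei - ej)) /
        (4 * h[i] * h[j])
    }
  }
  A <- 2 * solve(H)
  # gradient of each vcov diagonal element in the variance parameters
  grads <- matrix(0, p, k)
  vjj <- diag(rml(vp, "beta")$vcov)
  for (i in seq_len(k)) {
    ei <- replace(rep(0, k), i, h[i])
    up <- vp; up[free] <- pmax(vp[free] + ei, 1e-12)
    dn <- vp; dn[free] <- pmax(vp[free] - ei, 1e-12)
    grads[, i] <- (diag(rml(up, "beta")$vcov) - diag(rml(dn, "beta")$vcov)) /
      (2 * h[i])
  }
  df <- vapply(seq_len(p), function(j) {
    denom <- drop(grads[j, , drop = FALSE] %*% A %*% t(grads[j, , drop = FALSE]))
    if (denom <= 0) return(Inf)
    2 * vjj[j]^2 / denom
  }, numeric(1))
  pmin(pmax(df, 1), n * 100)
}

#' Single-term AIC screening of candidate model terms
#'
#' Each candidate is added singly to the base fixed-effect set. A candidate
#' is dropped iff its addition increases the ML AIC *and* it is not
#' statistically significant (smallest Wald p across its coefficients
#' >= 0.05); otherwise it is kept. The ledger records both quantities for
#' every candidate.
#'
#' @param data Joined modelling table as for [fit_lmm()].
#' @param base_terms Character vector of base fixed-effect columns.
#' @param candidates Character vector of candidate columns, disjoint from
#'   `base_terms`.
#' @param outcome Outcome column name.
#' @param alpha Significance threshold, default 0.05.
#' @return `data.table` `candidate, delta_aic, p, decision`.
#' @export
aic_screen <- function(data, base_terms, candidates,
                       outcome = "pm25_daily_mean", alpha = 0.05) {
  if (length(intersect(base_terms, candidates))) {
    stop("argument error: candidates must be disjoint from base terms",
         call. = FALSE)
  }
  miss <- setdiff(candidates, names(data))
  if (length(miss)) {
    stop("argument error: candidate(s) absent from data: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  out <- data.table::data.table(candidate = character(), delta_aic = numeric(),
                                p = numeric(), decision = character())
  if (!length(candidates)) return(out)
  base_fit <- fit_lmm(data, base_terms, outcome)
  for (cand in candidates) {
    fit <- fit_lmm(data, c(base_terms, cand), outcome)
    asg <- startsWith(fit$betas$term, cand)
    pmin_cand <- if (any(asg)) min(fit$betas$p[asg]) else NA_real_
    d_aic <- fit$aic - base_fit$aic
    dropped <- (d_aic > 0) && (is.na(pmin_cand) || pmin_cand >= alpha)
    out <- rbind(out, data.table::data.table(
      candidate = cand, delta_aic = d_aic, p = pmin_cand,
      decision = if (dropped) "dropped" else "kept"
    ))
  }
  out[]
}
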