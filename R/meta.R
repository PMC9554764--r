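# Random-effects meta-analytic synthesis of per-pair effects.
#
# DerSimonian-Laird pooling throughout: correlations on the Fisher-z scale
# with variance 1/(n_pairs - 3), regression and alpha effects on their raw
# scale with supplied standard errors. Subgroup (interaction-type) tests use
# the common-tau^2 mixed-effects convention: Q_between is the total
# random-effects Q minus the sum of within-group Qs, all computed with
# weights 1/(v + tau^2).

Z975 <- qnorm(0.975)

#' Fisher z transform with a boundary shrink
#'
#' Rank correlations over few site pairs can be exactly +/-1, where atanh is
#' infinite; such values are shrunk to +/- (1 - 1/(2 n)) before transforming
#' (the customary boundary correction, tied to the sample size that produced
#' the correlation).
#'
#' @param rho correlations in \[-1, 1\].
#' @param n per-correlation sample sizes (site-pair counts).
#' @return Fisher z values, always finite.
#' @export
fisher_z <- function(rho, n) {
  cap <- 1 - 1 / (2 * n)
  atanh(pmin(pmax(rho, -cap), cap))
}

# Core DL machinery on (y, v). Returns the pieces every pooling front-end needs.
dl_pool <- function(y, v) {
  k <- length(y)
  if (k == 1L)
    return(list(est = y, se = sqrt(v), tau2 = 0, Q = 0, df = 0, p_Q = NA_real_,
                k = 1L, w_re = 1 / v))
  w <- 1 / v
  ybar <- sum(w * y) / sum(w)
  Q <- sum(w * (y - ybar)^2)
  df <- k - 1L
  tau2 <- max(0, (Q - df) / (sum(w) - sum(w^2) / sum(w)))
  w_re <- 1 / (v + tau2)
  est <- sum(w_re * y) / sum(w_re)
  list(est = est, se = sqrt(1 / sum(w_re)), tau2 = tau2, Q = Q, df = df,
       p_Q = pchisq(Q, df, lower.tail = FALSE), k = k, w_re = w_re)
}

new_meta_result <- function(pool, ci95, extra = list()) {
  structure(c(list(estimate = pool$est, se = pool$se, ci95 = ci95,
                   tau2 = pool$tau2, Q = pool$Q, df = pool$df, p_Q = pool$p_Q,
                   k = pool$k), extra),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("Random-effects pooling (k = %d): estimate = %.4f [95%%: %.4f, %.4f], tau2 = %.4f, Q = %.3f (df = %d, p = %.3g)\n",
              x$k, x$estimate, x$ci95[1], x$ci95[2], x$tau2, x$Q, x$df, x$p_Q))
  if (!is.null(x$subgroup)) {
    cat(sprintf("  subgroup Q_between = %.3f (df = %d, p = %.3g)\n",
                x$subgroup$Q_between, x$subgroup$df_between,
                x$subgroup$p_between))
    print(round(x$subgroup$groups, 4))
  }
  invisible(x)
}

#' Pool per-pair correlations by random-effects meta-analysis
#'
#' Fisher-transforms each correlation (`z = atanh(rho)`, variance
#' `1/(n_pairs - 3)`), pools by DerSimonian-Laird, and back-transforms the
#' pooled estimate and its 95% CI with `tanh`. The effective n is the number
#' of site-pair comparisons, which ignores their non-independence and is
#' therefore anti-conservative in absolute terms; relative study weights are
#' what the pooling needs.
#'
#' @param rho numeric vector of per-pair Spearman correlations.
#' @param n_pairs integer vector of per-pair site-pair counts (each > 3).
#' @return A `meta_result` with the pooled correlation (back-transformed),
#'   `tau2`, `Q` on the z scale.
#' @export
pool_correlations <- function(rho, n_pairs) {
  if (length(rho) != length(n_pairs)) stop("rho and n_pairs must align")
  if (any(n_pairs <= 3)) stop("every study needs n_pairs > 3")
  z <- fisher_z(rho, n_pairs)
  v <- 1 / (n_pairs - 3)
  p <- dl_pool(z, v)
  ci <- tanh(c(p$est - Z975 * p$se, p$est + Z975 * p$se))
  out <- new_meta_result(p, ci, list(scale = "fisher-z", z = p$est))
  out$estimate <- tanh(p$est)
  out
}

#' Pool per-pair mean effects by random-effects meta-analysis
#'
#' DerSimonian-Laird pooling on the raw effect scale, for regression
#' coefficients (estimate, asymptotic SE) and alpha terms (posterior median,
#' posterior SD as SE).
#'
#' @param estimate numeric vector of per-pair effects.
#' @param se numeric vector of standard errors (> 0).
#' @return A `meta_result`.
#' @export
pool_means <- function(estimate, se) {
  if (length(estimate) != length(se)) stop("estimate and se must align")
  if (any(se <= 0)) stop("standard errors must be positive")
  p <- dl_pool(estimate, se^2)
  new_meta_result(p, c(p$est - Z975 * p$se, p$est + Z975 * p$se),
                  list(scale = "raw"))
}

# shared subgroup engine on (y, v, group): mixed-effects convention - the
# common tau^2 is the *residual* (within-group) DL estimate, so that real
# between-group separation is tested rather than absorbed into heterogeneity.
# Equivalent to the omnibus moderator test of a categorical mixed-effects
# meta-regression.
subgroup_q <- function(y, v, group) {
  p <- dl_pool(y, v)
  k <- length(y)
  groups <- unique(group)
  G <- length(groups)
  w <- 1 / v
  qw_fe <- 0
  C <- sum(w)
  for (g in groups) {
    idx <- group == g
    m <- sum(w[idx] * y[idx]) / sum(w[idx])
    qw_fe <- qw_fe + sum(w[idx] * (y[idx] - m)^2)
    C <- C - sum(w[idx]^2) / sum(w[idx])
  }
  tau2 <- if (k > G && C > 0) max(0, (qw_fe - (k - G)) / C) else 0
  ws <- 1 / (v + tau2)
  qtot <- sum(ws * (y - sum(ws * y) / sum(ws))^2)
  qwithin <- 0
  tab <- data.frame(group = groups, k = NA_integer_, estimate = NA_real_,
                    lo95 = NA_real_, hi95 = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(groups)) {
    idx <- group == groups[i]
    m <- sum(ws[idx] * y[idx]) / sum(ws[idx])
    qwithin <- qwithin + sum(ws[idx] * (y[idx] - m)^2)
    se_g <- sqrt(1 / sum(ws[idx]))
    tab$k[i] <- sum(idx)
    tab$estimate[i] <- m
    tab$lo95[i] <- m - Z975 * se_g
    tab$hi95[i] <- m + Z975 * se_g
  }
  qb <- max(0, qtot - qwithin)
  dfb <- G - 1L
  list(pool = p, Q_between = qb, df_between = dfb, tau2_common = tau2,
       p_between = pchisq(qb, dfb, lower.tail = FALSE), groups = tab)
}

#' Subgroup (interaction-type) test in a random-effects meta-analysis
#'
#' Tests whether pooled effects differ between groups (antagonists vs.
#' mutualists): with a common DL tau^2 across groups and random-effects
#' weights `w = 1/(v + tau^2)`, `Q_between = Q_total - sum_g Q_within_g`,
#' referred to chi-square with (groups - 1) df.
#'
#' @param estimate,se per-study effects and standard errors; for correlation
#'   effects pass Fisher-z values and `1/sqrt(n_pairs - 3)`.
#' @param group character vector of group labels (>= 2 groups, each
#'   non-empty).
#' @return A `meta_result` with a `subgroup` element (`Q_between`,
#'   `df_between`, `p_between`, per-group pooled table).
#' @export
subgroup_test <- function(estimate, se, group) {
  if (length(unique(group)) < 2) stop("need >= 2 groups")
  if (any(table(group) < 1)) stop("empty group")
  if (any(se <= 0)) stop("standard errors must be positive")
  sg <- subgroup_q(estimate, se^2, as.character(group))
  p <- sg$pool
  out <- new_meta_result(p, c(p$est - Z975 * p$se, p$est + Z975 * p$se),
                         list(scale = "raw"))
  out$subgroup <- sg[c("Q_between", "df_between", "p_between", "tau2_common",
                       "groups")]
  out
}

#' Close-relative pruning robustness scan
#'
#' Some associate taxa appear in two host-associate pairs (congeners or the
#' same species on two hosts). For g such relative groups, re-runs the
#' pooling on all 2^g datasets formed by excluding one member of each group,
#' and flags any pruned dataset whose qualitative conclusion (sign of the
#' pooled effect, 95% CI exclusion of zero, subgroup p < 0.05) differs from
#' the full-data result.
#'
#' @param effects data.frame with columns `pair_id`, `estimate`, `se`, and
#'   optionally `group` (for a subgroup test) and `relative_group` (NA or a
#'   group label; each label must tag exactly 2 rows).
#' @param pool_fun pooling function applied to each pruned dataset; receives
#'   the pruned data.frame, returns a `meta_result`. Default pools
#'   `estimate`/`se` via [pool_means()] (plus [subgroup_test()] when a
#'   `group` column is present).
#' @return list with `results` (one `meta_result` per pruned dataset,
#'   named by the excluded pair ids), `report` (data.frame of conclusions
#'   and flags), and `full` (the all-data result).
#' @export
prune_relatives_scan <- function(effects, pool_fun = NULL) {
  stopifnot(is.data.frame(effects), all(c("pair_id", "estimate", "se") %in%
                                          names(effects)))
  if (is.null(pool_fun)) {
    pool_fun <- function(d) {
      if (!is.null(d$group) && length(unique(d$group)) >= 2)
        subgroup_test(d$estimate, d$se, d$group)
      else pool_means(d$estimate, d$se)
    }
  }
  rg <- effects$relative_group
  if (is.null(rg)) rg <- rep(NA_character_, nrow(effects))
  groups <- sort(unique(rg[!is.na(rg)]))
  for (g in groups) if (sum(rg == g, na.rm = TRUE) != 2)
    stop(sprintf("relative group %s must have exactly 2 members", g))
  full <- pool_fun(effects)
  concl <- function(r) {
    c(sign = sign(r$estimate), sig = as.numeric(r$ci95[1] > 0 | r$ci95[2] < 0),
      sg = if (!is.null(r$subgroup)) as.numeric(r$subgroup$p_between < 0.05)
      else NA_real_)
  }
  base <- concl(full)
  if (!length(groups)) {
    report <- data.frame(excluded = "none", flagged = FALSE,
                         stringsAsFactors = FALSE)
    return(list(results = list(full), report = report, full = full))
  }
  choices <- expand.grid(rep(list(1:2), length(groups)))
  results <- vector("list", nrow(choices))
  report <- data.frame(excluded = character(nrow(choices)),
                       estimate = NA_real_, flagged = FALSE,
                       stringsAsFactors = FALSE)
  for (i in seq_len(nrow(choices))) {
    drop_ids <- vapply(seq_along(groups), function(j) {
      members <- effects$pair_id[!is.na(rg) & rg == groups[j]]
      members[choices[i, j]]
    }, "")
    d <- effects[!effects$pair_id %in% drop_ids, , drop = FALSE]
    r <- pool_fun(d)
    results[[i]] <- r
    cc <- concl(r)
    report$excluded[i] <- paste(drop_ids, collapse = "+")
    report$estimate[i] <- r$estimate
    report$flagged[i] <- !isTRUE(all.equal(unname(cc[!is.na(base)]),
                                           unname(base[!is.na(base)])))
  }
  names(results) <- report$excluded
  list(results = results, report = report, full = full)
}
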