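# End-to-end orchestration: per-pair analysis, cross-pair synthesis,
# manifests. Per-pair failures are isolated: a broken study is logged and
# skipped, mirroring the partial coverage typical of compiled literature
# data (not every pair supports every stage).

#' Pipeline control settings
#'
#' @param B_boot bootstrap resamples for correlation intervals.
#' @param n_perm MMRR permutations.
#' @param mcmc_config covariance-model config ([mcmc_desk_config()] or
#'   [mcmc_full_config()]).
#' @param run_covariance run the covariance-isolation stage on
#'   genotype-bearing pairs.
#' @return control list for [run_pair()] / [run_collection()].
#' @export
pipeline_control <- function(B_boot = 1000, n_perm = 1000,
                             mcmc_config = mcmc_full_config(),
                             run_covariance = TRUE) {
  list(B_boot = B_boot, n_perm = n_perm, mcmc_config = mcmc_config,
       run_covariance = run_covariance)
}

#' Desk-scale pipeline control (validation problem sizes)
#' @inheritParams pipeline_control
#' @return control list.
#' @export
desk_control <- function(B_boot = 200, n_perm = 100,
                         mcmc_config = mcmc_desk_config(n_iter = 2e4,
                                                        thin_to = 1000),
                         run_covariance = TRUE) {
  pipeline_control(B_boot, n_perm, mcmc_config, run_covariance)
}

#' Run all analysis stages for one host-associate pair
#'
#' Distances, then the correlation battery, the zero-inflated beta MMRR, and
#' (for genotype-bearing pairs) the covariance-isolation model. Emits one
#' tidy row per estimated effect for downstream meta-analysis.
#'
#' @param pair a [pair_dataset()].
#' @param control list from [pipeline_control()] / [desk_control()].
#' @param seed integer seed, expanded deterministically into per-stage seeds.
#' @return A `pair_report`: list with `effects` (data.frame: `pair_id`,
#'   `effect_type`, `estimate`, `se`, `n_pairs`, `group`, `relative_group`),
#'   the stage objects (`correlations`, `zib`, `mmrr`, `alpha`), `stages`
#'   run, and timings.
#' @export
run_pair <- function(pair, control = pipeline_control(), seed = 1L) {
  pair <- validate_pair(pair)
  t0 <- proc.time()[3]
  timings <- c()
  tick <- function(nm) {
    timings[nm] <<- proc.time()[3] - t0
    t0 <<- proc.time()[3]
  }
  geo_km <- great_circle_matrix(pair$sites)
  geo <- log10_geo(geo_km)
  climate <- if (pair$has_climate) climate_pca_distance(pair$sites)
  gmat <- function(obj)
    if (inherits(obj, "biallelic_counts")) pairwise_fst(obj) else obj
  host_gen <- gmat(pair$host)
  assoc_gen <- gmat(pair$associate)
  tick("distances")

  cors <- correlation_battery(pair, B = control$B_boot, seed = seed,
                              geo = geo, climate = climate,
                              host_gen = host_gen, assoc_gen = assoc_gen)
  tick("correlations")

  zib <- fit_zib(pair, geo = geo, climate = climate, host_gen = host_gen,
                 assoc_gen = assoc_gen)
  mmrr <- mmrr_test(zib, n_perm = control$n_perm, seed = seed + 1L)
  tick("regression")

  alpha <- NULL
  if (control$run_covariance && "covariance-model" %in% pair$stages) {
    E_list <- list()
    if (pair$has_climate) E_list$clim <- unclass(climate)
    E_list$host <- unclass(host_gen)
    alpha <- run_mcmc(pair$associate, unclass(geo_km), E_list,
                      config = control$mcmc_config, seed = seed + 2L)
    tick("covariance")
  }

  np <- length(zib$y)
  rg <- if (!is.null(pair$relative_group)) pair$relative_group else NA_character_
  row <- function(type, est, se = NA_real_)
    data.frame(pair_id = pair$pair_id, effect_type = type, estimate = est,
               se = se, n_pairs = np, group = pair$interaction_type,
               relative_group = rg, stringsAsFactors = FALSE)
  eff <- list(row("rho_host_ibd", cors$host_ibd$rho),
              row("rho_assoc_ibd", cors$assoc_ibd$rho),
              row("rho_host_assoc", cors$host_assoc$rho))
  if (pair$has_climate) {
    eff <- c(eff, list(row("rho_host_ibe", cors$host_ibe$rho),
                       row("rho_assoc_ibe", cors$assoc_ibe$rho)))
  }
  for (nm in setdiff(names(zib$beta), "(Intercept)"))
    eff <- c(eff, list(row(paste0("beta_", nm), zib$beta[[nm]], zib$se[[nm]])))
  if (!is.null(alpha)) {
    ps <- posterior_summary(alpha)
    amap <- c(alphaD = "alpha_geo", alphaE_clim = "alpha_clim",
              alphaE_host = "alpha_host")
    for (p in intersect(names(amap), rownames(ps)))
      eff <- c(eff, list(row(amap[[p]], ps[p, "median"], ps[p, "sd"])))
  }
  structure(list(pair_id = pair$pair_id, effects = do.call(rbind, eff),
                 correlations = cors, zib = zib, mmrr = mmrr, alpha = alpha,
                 stages = pair$stages, timings = timings),
            class = "pair_report")
}

#' @export
print.pair_report <- function(x, ...) {
  cat(sprintf("Pair report %s: stages [%s]\n", x$pair_id,
              paste(x$stages, collapse = ", ")))
  print(x$effects[, c("effect_type", "estimate", "se")], row.names = FALSE)
  invisible(x)
}

# pool one effect type (rho_* on the Fisher-z scale, others raw)
pool_effect <- function(eff, type) {
  d <- eff[eff$effect_type == type, , drop = FALSE]
  if (nrow(d) < 2) return(NULL)
  is_rho <- grepl("^rho_", type)
  res <- list()
  res$all <- if (is_rho) pool_correlations(d$estimate, d$n_pairs)
  else pool_means(d$estimate, d$se)
  for (g in unique(d$group)) {
    dg <- d[d$group == g, , drop = FALSE]
    if (nrow(dg) >= 2)
      res[[g]] <- if (is_rho) pool_correlations(dg$estimate, dg$n_pairs)
      else pool_means(dg$estimate, dg$se)
  }
  if (length(unique(d$group)) >= 2) {
    res$subgroup <- if (is_rho)
      subgroup_test(fisher_z(d$estimate, d$n_pairs),
                    1 / sqrt(d$n_pairs - 3), d$group)
    else subgroup_test(d$estimate, d$se, d$group)
  }
  res
}

#' Run a full collection: per-pair stages plus cross-pair synthesis
#'
#' Runs [run_pair()] on every study (failures are caught, logged, and
#' skipped), then pools each effect type by random-effects meta-analysis
#' (overall and within interaction types, with the subgroup test), runs the
#' publication-bias check on the host-associate correlations, and the
#' close-relative pruning scan on the focal effect types.
#'
#' @param collection list with `pairs` (and optionally `design`), e.g. from
#'   [simulate_collection()], or a bare list of [pair_dataset()]s.
#' @param control list from [pipeline_control()] / [desk_control()].
#' @param seed integer master seed; per-pair seeds are derived
#'   deterministically.
#' @return A `collection_report`: `effects` (all per-pair rows), `synthesis`
#'   (tidy pooled table), `pooled` (the `meta_result` objects by effect
#'   type), `publication_bias`, `prune` (robustness scans), `pair_reports`,
#'   `failures`, `manifest`.
#' @export
run_collection <- function(collection, control = pipeline_control(),
                           seed = 1L) {
  pairs <- if (!is.null(collection$pairs)) collection$pairs else collection
  if (length(pairs) < 2) stop("need >= 2 pairs")
  t_start <- proc.time()[3]
  reports <- list()
  failures <- list()
  for (i in seq_along(pairs)) {
    pid <- pairs[[i]]$pair_id
    r <- tryCatch(run_pair(pairs[[i]], control, seed = seed + 101L * i),
                  error = function(e) e)
    if (inherits(r, "error")) {
      failures[[pid]] <- conditionMessage(r)
      warning(sprintf("pair %s failed and was skipped: %s", pid,
                      conditionMessage(r)))
    } else reports[[pid]] <- r
  }
  if (length(reports) < 2) stop("fewer than 2 pairs completed")
  eff <- do.call(rbind, lapply(reports, `[[`, "effects"))
  rownames(eff) <- NULL

  types <- unique(eff$effect_type)
  pooled <- list()
  rows <- list()
  for (ty in types) {
    pe <- pool_effect(eff, ty)
    if (is.null(pe)) next
    pooled[[ty]] <- pe
    for (sc in setdiff(names(pe), "subgroup")) {
      r <- pe[[sc]]
      rows[[length(rows) + 1L]] <-
        data.frame(effect_type = ty, scope = sc, k = r$k,
                   estimate = r$estimate, lo95 = r$ci95[1], hi95 = r$ci95[2],
                   tau2 = r$tau2, Q = r$Q, p_Q = r$p_Q,
                   p_subgroup = if (!is.null(pe$subgroup) && sc == "all")
                     pe$subgroup$subgroup$p_between else NA_real_,
                   stringsAsFactors = FALSE)
    }
  }
  synthesis <- do.call(rbind, rows)
  rownames(synthesis) <- NULL

  ha <- eff[eff$effect_type == "rho_host_assoc", ]
  pub_bias <- if (nrow(ha) >= 4)
    publication_bias_test(ha$estimate, ha$n_pairs)

  prune <- list()
  for (ty in intersect(c("rho_host_assoc", "beta_host", "alpha_host"), types)) {
    d <- eff[eff$effect_type == ty, , drop = FALSE]
    if (nrow(d) < 3) next
    if (grepl("^rho_", ty)) {
      d$estimate <- fisher_z(d$estimate, d$n_pairs)
      d$se <- 1 / sqrt(d$n_pairs - 3)
    }
    if (all(is.na(d$relative_group))) next
    prune[[ty]] <- prune_relatives_scan(d)
  }

  manifest <- list(
    seed = seed,
    control = control,
    package_version = as.character(utils::packageVersion("hostassoc")),
    r_version = R.version.string,
    n_pairs_run = length(reports),
    n_pairs_failed = length(failures),
    stage_support = lapply(reports, `[[`, "stages"),
    wall_clock_s = unname(proc.time()[3] - t_start))
  structure(list(effects = eff, synthesis = synthesis, pooled = pooled,
                 publication_bias = pub_bias, prune = prune,
                 pair_reports = reports, failures = failures,
                 manifest = manifest),
            class = "collection_report")
}

#' @export
print.collection_report <- function(x, ...) {
  cat(sprintf("Collection report: %d pairs run, %d failed (%.1f s)\n",
              x$manifest$n_pairs_run, x$manifest$n_pairs_failed,
              x$manifest$wall_clock_s))
  print(transform(x$synthesis, estimate = round(estimate, 3),
                  lo95 = round(lo95, 3), hi95 = round(hi95, 3),
                  tau2 = round(tau2, 3), Q = round(Q, 2),
                  p_Q = signif(p_Q, 3), p_subgroup = signif(p_subgroup, 3)),
        row.names = FALSE)
  if (!is.null(x$publication_bias))
    cat(sprintf("publication-bias check: rho = %.3f, p = %.3g\n",
                x$publication_bias$rho, x$publication_bias$p))
  invisible(x)
}

#' Write a collection report to disk
#'
#' Emits the per-pair effects table, the synthesis table, the pruning
#' reports, and a JSON run manifest (seed, versions, config echo, checksums
#' of every written file).
#'
#' @param report a `collection_report`.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  w <- function(d, nm) {
    p <- file.path(dir, nm)
    write.csv(d, p, row.names = FALSE)
    files[nm] <<- unname(tools::md5sum(p))
  }
  w(report$effects, "effects.csv")
  w(report$synthesis, "synthesis.csv")
  for (ty in names(report$prune))
    w(report$prune[[ty]]$report, sprintf("prune_%s.csv", ty))
  manifest <- c(report$manifest, list(files = as.list(files)))
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(mp)
}
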