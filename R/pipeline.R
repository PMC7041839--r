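#' Pipeline configuration
#'
#' Collects everything one analysis run needs: either a [sim_config()] (the
#' study is simulated) or a directory of input files as written by
#' [write_study()], plus the thresholds and permutation settings used
#' downstream.
#'
#' @param sim A [sim_config()] to simulate inputs, or `NULL` when reading
#'   from `input_dir`.
#' @param input_dir Directory containing `fixes.csv`, `sites.csv`,
#'   `genotypes.csv`, ... (ignored when `sim` is given).
#' @param n_perm Permutations for every test (default 10000; must be >= 99).
#' @param mcp_levels Home-range percentages (default core area 50 and home
#'   range 95); each in (0, 100].
#' @param min_fixes_per_visit Visit-detection threshold (default 2).
#' @param related_threshold Relatedness cut-off defining "related pairs"
#'   for the filtered network (default 0.25).
#' @param seed Integer RNG seed; mandatory for reproducible permutation
#'   streams.
#' @param with_genotypes Set `FALSE` to skip all relatedness stages (e.g.
#'   networks-only runs when genotypes are unavailable).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), input_dir = NULL,
                            n_perm = 10000, mcp_levels = c(50, 95),
                            min_fixes_per_visit = 2,
                            related_threshold = 0.25, seed = 42,
                            with_genotypes = TRUE) {
  if (n_perm < 99) stop("`n_perm` must be >= 99", call. = FALSE)
  if (any(mcp_levels <= 0 | mcp_levels > 100)) {
    stop("`mcp_levels` must lie in (0, 100]", call. = FALSE)
  }
  if (is.null(sim) && (is.null(input_dir) || !dir.exists(input_dir))) {
    stop("either `sim` or an existing `input_dir` is required", call. = FALSE)
  }
  structure(
    list(sim = sim, input_dir = input_dir, n_perm = n_perm,
         mcp_levels = mcp_levels,
         min_fixes_per_visit = min_fixes_per_visit,
         related_threshold = related_threshold, seed = seed,
         with_genotypes = with_genotypes),
    class = "pipeline_config"
  )
}

#' Run the full analysis pipeline
#'
#' simulate (or ingest) -> visits -> home ranges -> relatedness ->
#' networks -> permutation inference -> report. Every stage writes its
#' artifacts under `out_dir`; the final `report.json` / `report.md`
#' assemble the result surface: per-season home-range summaries, the
#' relatedness distribution, per-season network metrics, MR-QAP of space
#' sharing against relatedness and co-roosting, seasonal node-metric
#' t-tests, and the degree ~ sites-visited regression. Runs are
#' deterministic given the config (seeded once at the start); a stage
#' failure aborts with the stage name after writing a partial manifest.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @return A list of class `pipeline_result` with the report and all
#'   intermediate objects, invisibly writing artifacts to `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  done <- character()
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      yaml::write_yaml(list(completed_stages = done, failed_stage = name,
                            error = conditionMessage(e)),
                       file.path(out_dir, "manifest.yaml"))
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    done <<- c(done, name)
    res
  }

  study <- stage("simulate", {
    if (!is.null(config$sim)) {
      st <- sim_study(config$sim)
      write_study(st, file.path(out_dir, "inputs"))
      st
    } else {
      read_study(config$input_dir)
    }
  })
  seasons <- unique(study$fixes$season)

  visits <- stage("visits", {
    v <- purrr::map(seasons, function(s) {
      fx <- study$fixes[study$fixes$season == s, ]
      dplyr::mutate(
        assign_visits(fx, study$landscapes[[s]],
                      min_fixes_per_visit = config$min_fixes_per_visit),
        season = s)
    }) |> dplyr::bind_rows()
    readr::write_csv(v, file.path(out_dir, "visits.csv"))
    v
  })

  hr <- stage("homerange", {
    h <- home_ranges(study$fixes, levels = config$mcp_levels)
    readr::write_csv(dplyr::select(h, -"polygon"),
                     file.path(out_dir, "homeranges.csv"))
    h
  })
  hr_summary <- purrr::map(config$mcp_levels, function(lv)
    seasonal_area_summary(hr, level = lv)$summary)
  names(hr_summary) <- paste0("level_", config$mcp_levels)

  rel <- NULL
  if (config$with_genotypes && !is.null(study$genotypes)) {
    rel <- stage("relatedness", {
      r <- ml_relatedness(study$genotypes)
      readr::write_csv(dplyr::select(r, -"loglik"),
                       file.path(out_dir, "relatedness.csv"))
      r
    })
  }

  nets <- stage("network", {
    out <- purrr::map(seasons, function(s) {
      vs <- visits[visits$season == s, ]
      net <- build_sharing_network(vs)
      readr::write_csv(tidy(net),
                       file.path(out_dir, sprintf("edges_%s.csv", s)))
      write_graphml(net, file.path(out_dir, sprintf("network_%s.graphml", s)))
      fnet <- if (!is.null(rel)) {
        filter_by_relatedness(net, rel, config$related_threshold)
      }
      coroost <- if (!is.null(study$roost_records)) {
        rr <- study$roost_records[study$roost_records$season == s, ]
        build_coroost_matrix(rr, ids = rownames(net$W))
      }
      list(net = net, fnet = fnet, coroost = coroost,
           metrics = network_metrics(net))
    })
    names(out) <- seasons
    metrics_tbl <- purrr::imap(out, function(o, s)
      dplyr::mutate(tidy(o$metrics), season = s)) |> dplyr::bind_rows()
    readr::write_csv(metrics_tbl, file.path(out_dir, "node_metrics.csv"))
    out
  })

  inference <- stage("inference", {
    res <- list()
    # MR-QAP: does relatedness / co-roosting predict space sharing?
    if (!is.null(rel)) {
      R <- relatedness_matrix(rel)
      res$qap <- purrr::imap(nets, function(o, s) {
        ids <- rownames(o$net$W)
        preds <- list(relatedness = R[ids, ids])
        if (!is.null(o$coroost)) preds$coroost <- o$coroost[ids, ids]
        # drop degenerate (constant) predictors, e.g. no co-roosting overlap
        preds <- preds[vapply(preds, function(m)
          diff(range(m[offdiag_idx(nrow(m))])) > 0, logical(1))]
        fit_full <- mrqap_dsp(o$net$W, preds, n_perm = config$n_perm)
        fit_filtered <- if (sum(o$fnet$W) > 0) {
          mrqap_dsp(o$fnet$W, list(relatedness = R[ids, ids]),
                    n_perm = config$n_perm)
        }
        list(full = fit_full, filtered = fit_filtered)
      })
    }
    # seasonal node-metric contrasts (two-season case)
    if (length(seasons) == 2L) {
      m <- purrr::imap(nets, function(o, s)
        dplyr::mutate(tidy(o$metrics), season = s)) |> dplyr::bind_rows()
      res$ttests <- purrr::map(
        c(k = "k", clustering = "clustering", strength = "strength"),
        function(col) node_perm_ttest(m[[col]], m$season,
                                      n_perm = config$n_perm))
    }
    # does the number of sites visited predict degree?
    sites_per_bat <- visits |>
      dplyr::group_by(.data$bat_id) |>
      dplyr::summarise(n_sites = dplyr::n_distinct(.data$site_id))
    m_all <- purrr::imap(nets, function(o, s) tidy(o$metrics)) |>
      dplyr::bind_rows() |>
      dplyr::left_join(sites_per_bat, by = "bat_id")
    res$degree_regression <- node_perm_regression(
      m_all$k, m_all$n_sites, n_perm = config$n_perm)
    # relatedness distribution contrast between seasons
    if (!is.null(rel) && length(seasons) == 2L) {
      season_of <- unlist(purrr::imap(
        purrr::map(nets, function(o) rownames(o$net$W)),
        function(ids, s) stats::setNames(rep(s, length(ids)), ids)))
      names(season_of) <- unlist(purrr::map(nets, function(o) rownames(o$net$W)))
      res$ks <- compare_r_distributions(rel, season_of,
                                        n_perm = config$n_perm)
    }
    res
  })

  report <- stage("report", {
    rep <- list(
      seasons = as.list(seasons),
      home_ranges = purrr::map(hr_summary, function(s)
        purrr::transpose(as.list(s))),
      network = purrr::imap(nets, function(o, s) as.list(glance(o$metrics))),
      degree_regression = list(
        slope = unname(inference$degree_regression$statistic[["slope"]]),
        adj_r_squared = inference$degree_regression$adj_r_squared,
        p = inference$degree_regression$p_value
      )
    )
    if (!is.null(rel)) {
      rep$relatedness_distribution <- as.list(
        table(cut(rel$r, breaks = seq(0, 1, 0.05), include.lowest = TRUE)))
      rep$qap <- purrr::map(inference$qap, function(q) list(
        full = list(r = q$full$r,
                    terms = purrr::transpose(as.list(q$full$coefficients))),
        filtered = if (!is.null(q$filtered)) {
          list(r = q$filtered$r, p = q$filtered$coefficients$p.value[1])
        } else list(r = NA, p = NA)
      ))
      rep$ks <- list(D = unname(inference$ks$statistic[["D"]]),
                     p = inference$ks$p_value)
    }
    if (!is.null(inference$ttests)) {
      rep$seasonal_ttests <- purrr::map(inference$ttests, function(tt) list(
        t = unname(tt$statistic[["t"]]), p = tt$p_value))
    }
    jsonlite::write_json(rep, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(render_report_md(rep), file.path(out_dir, "report.md"))
    rep
  })

  manifest <- list(
    seed = config$seed,
    n_perm = config$n_perm,
    mcp_levels = config$mcp_levels,
    min_fixes_per_visit = config$min_fixes_per_visit,
    related_threshold = config$related_threshold,
    completed_stages = done,
    counts = list(
      bats = length(unique(study$fixes$bat_id)),
      fixes = nrow(study$fixes),
      visits = nrow(visits),
      edges = sum(purrr::map_int(nets, function(o)
        sum(o$net$W[upper.tri(o$net$W)] > 0)))
    )
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))

  invisible(structure(
    list(report = report, visits = visits, home_ranges = hr,
         relatedness = rel, networks = nets, inference = inference,
         manifest = manifest, out_dir = out_dir),
    class = "pipeline_result"
  ))
}

render_report_md <- function(rep) {
  md <- c("# Foraging-network pipeline report", "")
  md <- c(md, "## Home ranges (ha) by season")
  for (lv in names(rep$home_ranges)) {
    md <- c(md, sprintf("- %s:", lv))
    for (row in rep$home_ranges[[lv]]) {
      md <- c(md, sprintf("  - %s: n = %d, median = %.2f [%.2f, %.2f]",
                          row$season, row$n, row$median_ha, row$q25_ha,
                          row$q75_ha))
    }
  }
  md <- c(md, "", "## Network metrics")
  for (s in names(rep$network)) {
    nw <- rep$network[[s]]
    md <- c(md, sprintf(
      "- %s: n = %d, density = %.3f, mean k = %.3f, mean C = %.3f, mean s = %.3f",
      s, nw$n, nw$density, nw$mean_k, nw$mean_clustering, nw$mean_strength))
  }
  if (!is.null(rep$qap)) {
    md <- c(md, "", "## MR-QAP (space sharing ~ relatedness [+ co-roosting])")
    for (s in names(rep$qap)) {
      q <- rep$qap[[s]]
      md <- c(md, sprintf("- %s: full-model r = %.3f; filtered-network r = %.3f (p = %.4g)",
                          s, q$full$r, q$filtered$r, q$filtered$p))
    }
  }
  md <- c(md, "", sprintf(
    "## Degree ~ sites visited: slope = %.4f, adj r^2 = %.3f, p = %.4g",
    rep$degree_regression$slope, rep$degree_regression$adj_r_squared,
    rep$degree_regression$p))
  md
}

#' Read a study directory written by [write_study()]
#'
#' @param dir Directory containing the CSV inputs.
#' @return A `sim_study`-shaped list (without pedigree/freqs when only the
#'   on-disk artifacts are available).
#' @export
read_study <- function(dir) {
  p <- function(f) file.path(dir, f)
  fixes <- readr::read_csv(p("fixes.csv"), show_col_types = FALSE)
  sites <- readr::read_csv(p("sites.csv"), show_col_types = FALSE)
  roosts <- readr::read_csv(p("roosts.csv"), show_col_types = FALSE)
  seasons <- unique(sites$season)
  landscapes <- purrr::map(seasons, function(s) {
    ss <- sites[sites$season == s, ]
    tree_cols <- setdiff(names(ss), c("season", "site_id", "x", "y", "radius"))
    trees <- tidyr::pivot_longer(ss[, c("site_id", tree_cols)], -"site_id",
                                 names_to = "species", values_to = "n_trees")
    trees <- dplyr::mutate(trees[trees$n_trees > 0, ], season = s)
    structure(
      list(sites = ss[, c("site_id", "x", "y", "radius")], trees = trees,
           roosts = roosts[roosts$season == s, c("roost_id", "x", "y")],
           extent = c(min(ss$x - ss$radius), max(ss$x + ss$radius),
                      min(ss$y - ss$radius), max(ss$y + ss$radius))),
      class = "landscape")
  })
  names(landscapes) <- seasons
  out <- list(fixes = fixes, landscapes = landscapes)
  if (file.exists(p("genotypes.csv"))) {
    out$genotypes <- read_genotypes(p("genotypes.csv"))
  }
  if (file.exists(p("roost_records.csv"))) {
    out$roost_records <- readr::read_csv(p("roost_records.csv"),
                                         show_col_types = FALSE)
  }
  if (file.exists(p("truth_visits.csv"))) {
    out$truth_visits <- readr::read_csv(p("truth_visits.csv"),
                                        show_col_types = FALSE)
  }
  out
}
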