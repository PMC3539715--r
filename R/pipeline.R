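# End-to-end pipeline: origins -> validation tests -> co-evolution ->
# shared selection -> gene sets -> enrichment -> degree statistics ->
# network weights, with per-stage TSV reports and a JSON run manifest.

#' Default pipeline configuration
#'
#' @param ... Named overrides. Key fields: `seed`; `simulate` (a
#'   [np_sim_config()] or list of overrides; used when no `inputs` are
#'   given); `inputs` (named list of file paths: `network`, `presence`,
#'   `tree`, `roles`, `branch_omega`, `gene_omega`, `annotations`);
#'   `n_null` (pseudo-pair replicates), `n_perm` (node-weight
#'   permutations), `n_rewire` (rewired networks), `cutoff`,
#'   `min_branches`, `shared_thresholds`, `clades` (for the removal scan;
#'   `NULL` skips it), `skip` (stage names to skip).
#' @return List of class `np_run_config`.
#' @export
np_run_config <- function(...) {
  cfg <- list(
    seed = 1L,
    simulate = list(),
    inputs = NULL,
    n_null = 200L,
    n_perm = 2000L,
    n_rewire = 200L,
    n_swaps_per_edge = 10,
    cutoff = 5,
    min_branches = 6L,
    shared_thresholds = c(1, 0.5),
    adapt_threshold = 0.5,
    clades = np_default_clades(),
    skip = character(0)
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ",
                        paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "np_run_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file.
#' @return An [np_run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(np_run_config, y)
}

.np_write_report <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Loads (or simulates) the inputs, then runs every analysis stage in
#' order, writing one TSV report per stage plus a `summary.txt` and a JSON
#' `manifest.json` recording the config snapshot, input digests, seeds,
#' package version, per-stage runtimes and output files. Any stage failure
#' aborts with a stage-tagged error; reports already written are retained.
#'
#' @param config An [np_run_config()] (or list of overrides, or a YAML
#'   path).
#' @param outdir Report directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_all <- function(config = np_run_config(), outdir) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "np_run_config")) {
    config <- do.call(np_run_config, config)
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  timings <- c(); outputs <- character(0); results <- list()
  stage <- function(name, fun) {
    if (name %in% config$skip) {
      .np_log("stage %s: skipped", name)
      timings[[name]] <<- NA_real_
      return(invisible(NULL))
    }
    tic <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e) {
      stop(sprintf("stage %s: %s", name, conditionMessage(e)), call. = FALSE)
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - tic, 3)
    results[[name]] <<- res
    invisible(res)
  }
  fp <- function(f) {
    p <- file.path(outdir, f); outputs <<- c(outputs, p); p
  }
  seed <- as.integer(config$seed)

  ## ingest ---------------------------------------------------------------
  input_files <- character(0)
  if (is.null(config$inputs)) {
    sim_cfg <- if (inherits(config$simulate, "sim_config")) config$simulate
               else do.call(np_sim_config,
                            c(config$simulate,
                              if (is.null(config$simulate$seed))
                                list(seed = seed)))
    simdir <- file.path(outdir, "simulated_inputs")
    fx <- make_study_fixture(sim_cfg, simdir)
    input_files <- fx$files
    net <- fx$net; presence <- fx$presence; phylo <- fx$phylo
    btab <- fx$branch_omega$table; gtab <- fx$gene_omega$table
    ann <- fx$annotations
  } else {
    inp <- config$inputs
    net <- read_network(inp$network)
    presence <- read_presence_matrix(inp$presence)
    phylo <- read_phylogeny(inp$tree, inp$roles)
    btab <- if (!is.null(inp$branch_omega)) read_branch_omega(inp$branch_omega)
    gtab <- if (!is.null(inp$gene_omega)) read_gene_omega(inp$gene_omega)
    ann <- if (!is.null(inp$annotations)) read_annotations(inp$annotations)
    input_files <- unlist(inp, use.names = FALSE)
  }

  ## origins ---------------------------------------------------------------
  census <- NULL
  stage("origins", function() {
    census <<- origin_census(net, presence, phylo)
    .np_write_report(data.frame(
      class = names(census$counts), new_pairs = unname(census$counts),
      fraction_at_node = unname(census$fractions)), fp("origin_census.tsv"))
    .np_write_report(census$pair_origins, fp("pair_origins.tsv"))
    census
  })
  stage("rates", function() {
    if (is.null(census)) stop("origins stage was skipped")
    losses <- lapply(np_branches("loss"), loss_rate, net = net,
                     presence = presence, phylo = phylo)
    gains <- lapply(np_branches("origin")[-1], gain_rate, census = census,
                    phylo = phylo)
    rt <- do.call(rbind, lapply(c(losses, gains), function(r) {
      data.frame(type = r$type, branch = r$branch, events = r$events,
                 exposure = r$exposure, ks = r$ks, rate = r$rate,
                 stringsAsFactors = FALSE)
    }))
    g_max_loss <- max(vapply(losses, function(r) r$rate, numeric(1)))
    ss <- steady_state_correction(g_max_loss, census, phylo)
    .np_write_report(rt, fp("rates.tsv"))
    .np_write_report(data.frame(
      raw_root_fraction = ss$raw, corrected_root_fraction = ss$corrected,
      assumed_gain_rate = ss$g, method = ss$method),
      fp("steady_state.tsv"))
    list(rates = rt, steady_state = ss)
  })
  stage("concerted", function() {
    ct <- concerted_presence_test(net, presence, n_null = config$n_null,
                                  seed = seed + 1000L)
    df <- data.frame(species = rownames(ct$status_counts),
                     ct$status_counts, check.names = FALSE)
    df$concordant <- df$`4` + df$`0`
    df$p <- vapply(df$species, function(s) format_p(ct$per_species[[s]]),
                   character(1))
    .np_write_report(df, fp("concerted_presence.tsv"))
    ct
  })
  stage("degree_age", function() {
    da <- degree_age_correlation(net, presence, phylo,
                                 n_null = config$n_null,
                                 seed = seed + 2000L)
    tab <- da$table
    tab$pearson_r <- da$test$observed
    tab$p <- format_p(da$test)
    .np_write_report(tab, fp("degree_age.tsv"))
    da
  })

  ## co-evolution ----------------------------------------------------------
  stage("coevolution", function() {
    if (is.null(btab)) stop("no branch omega table supplied")
    if (is.null(config$clades)) {
      res <- mean_rho_test(net, btab, n_null = config$n_null,
                           cutoff = config$cutoff,
                           min_branches = config$min_branches,
                           seed = seed + 3000L)
      scan <- list(results = list(None = res),
                   table = data.frame(clade = "None", n_ppis = res$n_pairs,
                                      p = format_p(res$test),
                                      mean_rho = res$mean_rho,
                                      mean_of_means = res$mean_of_means,
                                      difference = res$difference,
                                      stringsAsFactors = FALSE))
    } else {
      scan <- clade_removal_scan(net, btab, clades = config$clades,
                                 n_null = config$n_null,
                                 cutoff = config$cutoff,
                                 min_branches = config$min_branches,
                                 seed = seed + 3000L)
    }
    .np_write_report(scan$table, fp("coevolution.tsv"))
    scan
  })
  stage("shared_selection", function() {
    if (is.null(btab)) stop("no branch omega table supplied")
    for (th in config$shared_thresholds) {
      sc <- shared_selection_scan(net, btab, threshold = th)
      .np_write_report(sc, fp(sprintf("shared_selection_%g.tsv", th)))
    }
    invisible(NULL)
  })

  ## gene sets, enrichment, degree statistics ------------------------------
  sets <- NULL
  stage("gene_sets", function() {
    if (is.null(census)) stop("origins stage was skipped")
    sets <<- define_gene_sets(census, net, btab,
                              threshold = config$adapt_threshold)
    .np_write_report(do.call(rbind, lapply(sets, function(s) {
      data.frame(set = s$id, n_members = length(s$members),
                 n_complement = length(s$complement),
                 stringsAsFactors = FALSE)
    })), fp("gene_sets.tsv"))
    sets
  })
  stage("enrichment", function() {
    if (is.null(sets)) stop("gene_sets stage was skipped")
    if (is.null(ann)) stop("no annotation table supplied")
    for (s in sets) {
      # Bonferroni on by default; the AdaptI contrast reports raw p too
      er <- hypergeometric_enrichment(s, ann, bonferroni = TRUE)
      .np_write_report(er, fp(sprintf("enrichment_%s.tsv", s$id)))
    }
    invisible(NULL)
  })
  stage("degree_stats", function() {
    if (is.null(sets)) stop("gene_sets stage was skipped")
    pp <- sets$PrimPresI; pu <- sets$PrimUniqI
    cs1 <- compare_degree_sets(pp$members, pp$complement, net)
    cs2 <- compare_degree_sets(pu$members, pu$complement, net)
    tab <- rbind(
      cbind(contrast = "PrimPresI vs rest", cs1$summary, p = cs1$p),
      cbind(contrast = "PrimUniqI vs rest", cs2$summary, p = cs2$p))
    .np_write_report(tab, fp("degree_stats.tsv"))
    po <- if (!is.null(census)) census$pair_origins else NULL
    dd <- NULL
    if (!is.null(po)) {
      prim <- po$origin %in% c("primates", "human-chimp", "human")
      if (any(prim) && any(!prim)) {
        dd <- compare_degree_difference_sets(po[prim, c("a", "b")],
                                             po[!prim, c("a", "b")], net)
        .np_write_report(data.frame(
          set = c("primate-specific", "nonprimate"),
          n = c(length(dd$dkA), length(dd$dkB)),
          mean_delta_k = c(dd$mean_dkA, dd$mean_dkB),
          max_delta_k = c(max(dd$dkA), max(dd$dkB)),
          wilcoxon_p = dd$p), fp("degree_difference.tsv"))
      }
    }
    list(sets = tab, degree_difference = dd)
  })

  ## network weights --------------------------------------------------------
  stage("netweight", function() {
    if (is.null(gtab)) stop("no global omega table supplied")
    cw <- constraint_assortativity_test(net, gtab, n_perm = config$n_perm,
                                        seed = seed + 4000L)
    dw <- degree_assortativity_test(net, n_rewire = config$n_rewire,
                                    n_swaps_per_edge = config$n_swaps_per_edge,
                                    seed = seed + 5000L)
    .np_write_report(do.call(rbind, lapply(list(cw, dw), function(x) {
      data.frame(statistic = x$weight_id, observed_w = x$w,
                 null_mean = x$null_mean,
                 null_sd = stats::sd(x$null_w),
                 p = format_p(x$test), direction = x$test$direction,
                 n_perm = x$n_perm, seed = x$seed,
                 stringsAsFactors = FALSE)
    })), fp("network_weight.tsv"))
    list(constraint = cw, degree = dw)
  })

  ## summary + manifest -----------------------------------------------------
  summary_path <- fp("summary.txt")
  con <- file(summary_path, open = "wt")
  sink(con)
  cat("netpaleo pipeline summary\n=========================\n\n")
  print(net)
  for (nm in names(results)) {
    cat("\n-- ", nm, " --\n", sep = "")
    r <- results[[nm]]
    if (inherits(r, "origin_census") || inherits(r, "concerted_test") ||
        inherits(r, "degree_age_test") || inherits(r, "clade_scan")) print(r)
    else if (nm == "rates") {
      print(r$steady_state)
    } else if (nm == "netweight") {
      print(r$constraint); print(r$degree)
    } else cat("see report files\n")
  }
  sink()
  close(con)

  digests <- tryCatch(
    as.list(tools::md5sum(input_files[file.exists(input_files)])),
    error = function(e) list())
  cfg_snapshot <- unclass(config)[setdiff(names(config), "clades")]
  cfg_snapshot$simulate <- unclass(cfg_snapshot$simulate)
  manifest <- list(
    package_version = as.character(utils::packageVersion("netpaleo")),
    seed = seed,
    config = cfg_snapshot,
    input_digests = digests,
    stage_runtime_s = as.list(timings),
    outputs = basename(outputs))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(list(results = results, manifest = manifest, outdir = outdir))
}
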