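# Orchestration: the full analysis (rate comparisons i-iv across taxonomic
# groups and hardening strata, absolute rates with four-model AIC selection,
# PGLS panels) driven by a single config, with seeded determinism and
# two-decimal display tables plus full-precision companions.

COMPARISONS <- list(i = c("T_min", "MTCM"), ii = c("T_max", "MTWM"),
                    iii = c("T_min", "T_max"), iv = c("MTCM", "MTWM"))

#' Build an analysis configuration
#'
#' Inputs may be in-memory objects (a `phylo`, data frames) or file paths
#' (Newick, TSV, ESRI ASCII grids); paths are loaded lazily when the analysis
#' runs. Supply either `occurrences` (summarized internally) or a
#' pre-summarized `niche_table`.
#'
#' @param tree `phylo` or path to a Newick file.
#' @param traits Trait table (species, T_min, T_max, hardening, group) or
#'   path.
#' @param occurrences Occurrence table (species, longitude, latitude, bio5,
#'   bio6) or path; optional if `niche_table` given.
#' @param niche_table Pre-summarized niche table or path; optional.
#' @param niche_variant `"mean"`, `"tail"`, or `"local"`.
#' @param comparisons Which of the paired comparisons to run: subset of
#'   `c("i", "ii", "iii", "iv")` — i: T_min vs MTCM, ii: T_max vs MTWM,
#'   iii: T_min vs T_max, iv: MTCM vs MTWM.
#' @param groups Taxonomic strata; `"all"` plus group labels.
#' @param hardening_types Hardening strata; `"all"`, `"hardened"`,
#'   `"non_hardened"`, `"unknown"`.
#' @param lambda_mode,lambda PGLS lambda handling (see [pgls_fit()]).
#' @param min_n Minimum stratum size for any test (default 3).
#' @param out_dir Optional output directory for result tables.
#' @param seed Seed recorded in the manifest (analyses are deterministic
#'   given the inputs; the seed matters when the config is used to simulate).
#' @return List of class `analysis_config`.
#' @export
analysis_config <- function(tree, traits, occurrences = NULL,
                            niche_table = NULL,
                            niche_variant = "mean",
                            comparisons = c("i", "ii", "iii", "iv"),
                            groups = c("all", "angiosperm", "gymnosperm",
                                       "fern"),
                            hardening_types = c("all", "hardened",
                                                "non_hardened", "unknown"),
                            lambda_mode = "fixed", lambda = 1,
                            min_n = 3L, out_dir = NULL, seed = 1L) {
  if (is.null(occurrences) && is.null(niche_table))
    stop("supply occurrences or a niche_table")
  comparisons <- match.arg(comparisons, names(COMPARISONS),
                           several.ok = TRUE)
  structure(list(tree = tree, traits = traits, occurrences = occurrences,
                 niche_table = niche_table, niche_variant = niche_variant,
                 comparisons = comparisons, groups = groups,
                 hardening_types = hardening_types,
                 lambda_mode = lambda_mode, lambda = lambda,
                 min_n = as.integer(min_n), out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

#' Read a flat key=value analysis config file
#'
#' One `key=value` per line, `#` comments allowed. Recognized keys: `tree`,
#' `traits`, `occurrences`, `niche_table`, `niche_variant`, `comparisons`
#' (comma-separated), `lambda_mode`, `lambda`, `min_n`, `out`, `seed`.
#'
#' @param path Config file path.
#' @return An `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, function(x)
    trimws(paste(x[-1L], collapse = "=")), character(1)),
    vapply(kv, function(x) trimws(x[1L]), character(1)))
  get <- function(k, default = NULL) if (k %in% names(vals)) vals[[k]]
                                     else default
  analysis_config(
    tree = get("tree"), traits = get("traits"),
    occurrences = get("occurrences"), niche_table = get("niche_table"),
    niche_variant = get("niche_variant", "mean"),
    comparisons = strsplit(get("comparisons", "i,ii,iii,iv"), ",")[[1L]],
    lambda_mode = get("lambda_mode", "fixed"),
    lambda = as.numeric(get("lambda", "1")),
    min_n = as.integer(get("min_n", "3")),
    out_dir = get("out"), seed = as.integer(get("seed", "1")))
}

# Materialize config inputs: load paths, summarize occurrences, assemble the
# species-level table.
#' @keywords internal
load_inputs <- function(config) {
  tree <- config$tree
  if (is.character(tree)) tree <- parse_newick(paste(readLines(tree),
                                                     collapse = ""))
  traits <- config$traits
  if (is.character(traits)) traits <- read_table_tsv(traits)
  niches <- config$niche_table
  if (is.character(niches)) niches <- read_table_tsv(niches)
  if (is.null(niches)) {
    occ <- config$occurrences
    if (is.character(occ)) occ <- read_table_tsv(occ)
    niches <- summarize_niche(occ)
  }
  tab <- assemble_analysis_table(traits, niches,
                                 niche_variant = config$niche_variant)
  in_tree <- tab$species %in% tree$tip.label
  if (!all(in_tree))
    message(sum(!in_tree), " species not in the tree were dropped")
  tab <- tab[in_tree, , drop = FALSE]
  list(tree = tree, table = tab)
}

#' @keywords internal
stratum_rows <- function(tab, group, type) {
  keep <- rep(TRUE, nrow(tab))
  if (group != "all") keep <- keep & !is.na(tab$group) & tab$group == group
  if (type != "all") keep <- keep & tab$hardening == type
  tab[keep, , drop = FALSE]
}

#' Overall-rate comparisons across groups and hardening strata
#'
#' For every (group, hardening type, comparison) stratum: prune the tree to
#' the species carrying both traits, run the common-rate vs separate-rates
#' likelihood-ratio test, and report N, both rates, the LRT statistic and p.
#' Strata below `min_n` are emitted as NA rows (rendered "–" in the
#' two-decimal display table). The pruned-tree height per stratum is included
#' so branch-length scaling across groups stays auditable.
#'
#' @param config An [analysis_config()].
#' @return Data frame: `group`, `type`, `comparison`, `trait_A`, `trait_B`,
#'   `N`, `sigma2_A`, `sigma2_B`, `LRT`, `p_value`, `faster_trait`,
#'   `tree_height`.
#' @export
run_overall_rates <- function(config) {
  inp <- load_inputs(config)
  rows <- list()
  for (grp in config$groups) for (ty in config$hardening_types) {
    sub <- stratum_rows(inp$table, grp, ty)
    for (cmp in config$comparisons) {
      pair <- COMPARISONS[[cmp]]
      xA <- stats::setNames(sub[[pair[1L]]], sub$species)
      xB <- stats::setNames(sub[[pair[2L]]], sub$species)
      n_ok <- sum(!is.na(xA) & !is.na(xB))
      if (n_ok < config$min_n) {
        rows[[length(rows) + 1L]] <- data.frame(
          group = grp, type = ty, comparison = cmp,
          trait_A = pair[1L], trait_B = pair[2L], N = n_ok,
          sigma2_A = NA_real_, sigma2_B = NA_real_, LRT = NA_real_,
          p_value = NA_real_, faster_trait = NA_character_,
          tree_height = NA_real_, stringsAsFactors = FALSE)
        next
      }
      r <- lrt_rate_comparison(inp$tree, xA, xB, pair[1L], pair[2L])
      rows[[length(rows) + 1L]] <- data.frame(
        group = grp, type = ty, comparison = cmp,
        trait_A = pair[1L], trait_B = pair[2L], N = r$n_species,
        sigma2_A = r$sigma2_A, sigma2_B = r$sigma2_B, LRT = r$LRT,
        p_value = r$p_value, faster_trait = r$faster_trait,
        tree_height = r$tree_height, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  maybe_write(out, config, "overall_rates")
  out
}

#' Absolute-rate analysis: model selection, ASR, tip rates, paired tests
#'
#' For each (group, hardening type) stratum and each trait with data: fit the
#' four models (OU/LA only at ≥ 4 tips), select by AIC, reconstruct ancestors
#' on the best-model-transformed structure, and compute per-tip absolute
#' rates. Then for every requested comparison, the species-level paired
#' t-test on ln rates.
#'
#' @param config An [analysis_config()].
#' @return List: `model_selection` (stratum × trait best-model table),
#'   `tests` (paired test results), `tip_rates` (long table).
#' @export
run_absolute_rates <- function(config) {
  inp <- load_inputs(config)
  traits4 <- c("T_min", "T_max", "MTCM", "MTWM")
  sel_rows <- list(); test_rows <- list(); rate_rows <- list()
  for (grp in config$groups) for (ty in config$hardening_types) {
    sub <- stratum_rows(inp$table, grp, ty)
    rates <- list()
    for (tr in traits4) {
      x <- stats::setNames(sub[[tr]], sub$species)
      x <- x[!is.na(x)]
      x <- x[names(x) %in% inp$tree$tip.label]
      if (length(x) < max(config$min_n, 3L)) next
      ptree <- prune_to_taxa(inp$tree, names(x))
      if (stats::var(x) == 0) {
        sel_rows[[length(sel_rows) + 1L]] <- data.frame(
          group = grp, type = ty, trait = tr, n = length(x),
          best_model = NA_character_, sigma2 = 0, AIC = NA_real_,
          note = "constant trait; skipped", stringsAsFactors = FALSE)
        next
      }
      fits <- fit_all_models(ptree, x)
      best <- select_model(fits)
      anc <- reconstruct_ancestors(ptree, x, best)
      rt <- tip_absolute_rates(ptree, x, anc, trait_name = tr)
      rates[[tr]] <- rt
      sel_rows[[length(sel_rows) + 1L]] <- data.frame(
        group = grp, type = ty, trait = tr, n = length(x),
        best_model = best$model, sigma2 = best$sigma2, AIC = best$AIC,
        note = if (length(fits) < 4L) "OU/LA skipped (n < 4)" else "",
        stringsAsFactors = FALSE)
      rate_rows[[length(rate_rows) + 1L]] <-
        cbind(group = grp, type = ty, rt)
    }
    for (cmp in config$comparisons) {
      pair <- COMPARISONS[[cmp]]
      if (is.null(rates[[pair[1L]]]) || is.null(rates[[pair[2L]]])) next
      res <- tryCatch(paired_rate_test(rates[[pair[1L]]],
                                       rates[[pair[2L]]]),
                      error = function(e) NULL)
      if (is.null(res)) next
      test_rows[[length(test_rows) + 1L]] <- data.frame(
        group = grp, type = ty, comparison = cmp,
        trait_A = pair[1L], trait_B = pair[2L], m = res$m,
        mean_ln_rate_A = res$mean_ln_rate_A,
        mean_ln_rate_B = res$mean_ln_rate_B,
        t_statistic = res$t_statistic, df = res$df,
        p_value = res$p_value, n_excluded_zero = res$n_excluded_zero,
        stringsAsFactors = FALSE)
    }
  }
  out <- list(model_selection = do.call(rbind, sel_rows),
              tests = do.call(rbind, test_rows),
              tip_rates = do.call(rbind, rate_rows))
  maybe_write(out$model_selection, config, "absrate_model_selection")
  maybe_write(out$tests, config, "absrate_tests")
  maybe_write(out$tip_rates, config, "tip_rates")
  out
}

#' PGLS panels of tolerance against niche
#'
#' Runs [figure4_panels()] on the assembled analysis table.
#'
#' @param config An [analysis_config()].
#' @return The panel results data frame.
#' @export
run_pgls <- function(config) {
  inp <- load_inputs(config)
  out <- figure4_panels(inp$table, inp$tree,
                        lambda_mode = config$lambda_mode,
                        lambda = config$lambda)
  maybe_write(out, config, "pgls_panels")
  out
}

#' Run the full analysis
#'
#' Overall rates, absolute rates, and PGLS in sequence; when `out_dir` is
#' set, every table is written twice (2-decimal display and full precision)
#' plus a run manifest with the seed and options.
#'
#' @param config An [analysis_config()].
#' @return List with `overall_rates`, `absolute_rates`, `pgls`.
#' @export
run_all <- function(config) {
  res <- list(overall_rates = run_overall_rates(config),
              absolute_rates = run_absolute_rates(config),
              pgls = run_pgls(config))
  if (!is.null(config$out_dir)) {
    writeLines(c(paste0("seed=", config$seed),
                 paste0("niche_variant=", config$niche_variant),
                 paste0("lambda_mode=", config$lambda_mode),
                 paste0("comparisons=",
                        paste(config$comparisons, collapse = ",")),
                 paste0("R_version=", R.version.string)),
               file.path(config$out_dir, "run_manifest.txt"))
  }
  res
}

#' @keywords internal
maybe_write <- function(tab, config, name) {
  if (is.null(config$out_dir) || is.null(tab)) return(invisible(NULL))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_table_tsv(tab, file.path(config$out_dir,
                                 paste0(name, "_full.tsv")))
  disp <- tab
  disp[] <- lapply(disp, function(col)
    if (is.numeric(col))
      ifelse(is.na(col), "–", formatC(round(col, 2), format = "fg"))
    else ifelse(is.na(col), "–", col))
  utils::write.table(disp, file.path(config$out_dir, paste0(name, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic scenario), `niche` (summarize
#' occurrences), `rates`, `absrates`, `pgls`, `run-all`. Flags: `--config`
#' (key=value file for the analysis subcommands), `--seed`, `--out`,
#' `--niche-variant`, `--lambda-mode`, `--n` (simulate). Logs go to stderr.
#'
#' Invoke as
#' `Rscript -e 'thermorates::thermo_cli()' simulate --seed 1 --out dir`.
#'
#' @param args Command-line arguments; defaults to
#'   `commandArgs(trailingOnly = TRUE)`.
#' @return Exit status 0 invisibly on success.
#' @export
thermo_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L)
    stop("usage: <simulate|niche|rates|absrates|pgls|run-all> [--flags]")
  cmd <- args[1L]; args <- args[-1L]
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    if (startsWith(args[i], "--")) {
      flags[[sub("^--", "", args[i])]] <- args[i + 1L]
      i <- i + 2L
    } else i <- i + 1L
  }
  gf <- function(k, default = NULL) if (k %in% names(flags)) flags[[k]]
                                    else default
  log_msg <- function(...) message("[thermorates] ", ...)
  if (cmd == "simulate") {
    seed <- as.integer(gf("seed", "1"))
    n <- as.integer(gf("n", "300"))
    out <- gf("out", "scenario")
    sc <- make_study_scenario(scenario_config(n_species = n), seed)
    write_scenario(sc, out)
    log_msg("scenario (n = ", n, ", seed = ", seed, ") written to ", out)
    return(invisible(0L))
  }
  if (cmd == "niche") {
    occ <- read_table_tsv(gf("occurrences"))
    out <- gf("out", "niche_summary.tsv")
    write_table_tsv(summarize_niche(occ), out)
    log_msg("niche summaries written to ", out)
    return(invisible(0L))
  }
  if (!cmd %in% c("rates", "absrates", "pgls", "run-all"))
    stop("unknown subcommand: ", cmd)
  if (is.null(gf("config"))) stop(cmd, " requires --config")
  cfg <- read_analysis_config(gf("config"))
  if (!is.null(gf("out"))) cfg$out_dir <- gf("out")
  if (!is.null(gf("seed"))) cfg$seed <- as.integer(gf("seed"))
  if (!is.null(gf("niche-variant"))) cfg$niche_variant <- gf("niche-variant")
  if (!is.null(gf("lambda-mode"))) cfg$lambda_mode <- gf("lambda-mode")
  res <- switch(cmd,
    rates = run_overall_rates(cfg),
    absrates = run_absolute_rates(cfg),
    pgls = run_pgls(cfg),
    "run-all" = run_all(cfg))
  log_msg(cmd, " finished",
          if (!is.null(cfg$out_dir)) paste0("; results in ", cfg$out_dir))
  invisible(0L)
}
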