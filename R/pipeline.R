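## End-to-end pipeline driver: configuration validation, stage execution,
## and publication-style outputs (model tables, shift tables, histogram and
## LTT data) written as JSON plus TSV mirrors.  The R functions are the
## primary interface; this driver exists so a whole analysis is one
## reproducible call with a seed and a config echoed into every output.

validate_config <- function(config) {
  if (!is.list(config)) stop("config must be a list")
  stages_known <- c("simulate", "bisse", "medusa", "sisters", "ltt")
  if (is.null(config$stages) || !length(config$stages))
    stop("config must request at least one stage")
  bad <- setdiff(config$stages, stages_known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (is.null(config$seed)) stop("config must carry a seed")
  if (is.null(config$out_dir)) stop("config must name an output directory")
  if (!("simulate" %in% config$stages) && is.null(config$tree))
    stop("config needs an input tree unless the simulate stage is requested")
  config
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, force = TRUE,
                              digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the configured analysis pipeline
#'
#' Executes the requested stages in order `simulate` -> (`bisse`,
#' `medusa`, `sisters`, `ltt`), writing `results.json` plus TSV tables to
#' `config$out_dir`.  Every output embeds the seed and an MD5 hash of the
#' config for provenance; re-running with the same config and seed
#' reproduces the bundle exactly.
#'
#' Config fields: `seed`, `out_dir`, `stages` (character vector); `tree` /
#' `tips` (file paths, or in-memory objects) unless simulating;
#' `mode`/`f` for tip tables read from file; optional per-stage lists
#' `simulate` (arguments of [simulate_bisse_tree()]), `bisse` (`models`,
#' `root_mode`, `condition`), `medusa` (`threshold`, `max_shifts`,
#' `condition`), `ltt`.
#'
#' @param config a named list (see Details above).
#' @return the result bundle, invisibly: list of per-stage results.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  bundle <- list(config = config, config_hash = config_hash(config),
                 seed = config$seed, timings = list())
  tic <- function() proc.time()[["elapsed"]]
  phy <- NULL; tips <- NULL
  if (!is.null(config$tree)) {
    phy <- if (inherits(config$tree, "phylo")) as_timetree(config$tree)
           else read_tree(config$tree)
    if (!is.null(config$tips)) {
      tips <- if (inherits(config$tips, "tip_data")) config$tips
              else read_tip_data(config$tips,
                                 mode = config$mode %||% "proportional",
                                 f = config$f %||% 1)
    }
  }
  if ("simulate" %in% config$stages) {
    t0 <- tic()
    sim_args <- config$simulate %||% list(max_tips = 200L)
    sim <- do.call(simulate_bisse_tree, sim_args)
    phy <- sim$tree; tips <- sim$tips
    write_tree(phy, file.path(config$out_dir, "simulated_tree.nwk"))
    write_tip_data(tips, file.path(config$out_dir, "simulated_tips.tsv"))
    bundle$simulate <- list(n_tip = ape::Ntip(phy),
                            n_attempts = sim$n_attempts)
    bundle$timings$simulate <- tic() - t0
  }
  if (is.null(tips) && !is.null(phy))
    tips <- tip_data(phy$tip.label, NA, mode = "proportional", f = 1)
  if ("bisse" %in% config$stages) {
    t0 <- tic()
    opts <- config$bisse %||% list()
    models <- opts$models %||% c("equal_div", "full")
    fits <- lapply(models, function(m)
      fit_model(phy, tips, model = m,
                root_mode = opts$root_mode %||% "weighted",
                condition_on_survival = isTRUE(opts$condition)))
    names(fits) <- models
    cmp <- compare_models(fits)
    bundle$bisse <- list(fits = fits, comparison = cmp)
    par_tab <- do.call(rbind, lapply(fits, function(f)
      data.frame(model = f$model, t(unclass(f$pars)), r0 = f$net_rates["r0"],
                 r1 = f$net_rates["r1"], lnL = f$lnL, row.names = NULL)))
    write_tsv(par_tab, file.path(config$out_dir, "bisse_models.tsv"))
    if (!is.null(cmp$lrt))
      write_tsv(cmp$lrt, file.path(config$out_dir, "bisse_lrt.tsv"))
    bundle$timings$bisse <- tic() - t0
  }
  if ("medusa" %in% config$stages) {
    t0 <- tic()
    opts <- config$medusa %||% list()
    rich <- richness_data(phy, tips)
    search <- stepwise_search(phy, rich,
                              threshold = opts$threshold %||% 8.4547,
                              max_shifts = opts$max_shifts %||% 20L,
                              condition = opts$condition %||% TRUE)
    bundle$medusa <- search
    write_tsv(shift_table(search),
              file.path(config$out_dir, "medusa_shifts.tsv"))
    bundle$timings$medusa <- tic() - t0
  }
  if ("sisters" %in% config$stages) {
    t0 <- tic()
    sc <- tryCatch(sister_contrasts(phy, tips), error = function(e) e)
    if (inherits(sc, "error")) {
      bundle$sisters <- list(error = conditionMessage(sc))
    } else {
      bundle$sisters <- sc
      write_tsv(sc$pairs, file.path(config$out_dir, "sister_pairs.tsv"))
    }
    bundle$timings$sisters <- tic() - t0
  }
  if ("ltt" %in% config$stages) {
    t0 <- tic()
    curves <- list(all = ltt_curve(phy))
    for (s in 0:1) {
      cv <- tryCatch(ltt_curve(phy, tips, state = s), error = function(e) NULL)
      if (!is.null(cv)) curves[[paste0("state", s)]] <- cv
    }
    tab <- do.call(rbind, lapply(names(curves), function(nm)
      cbind(curve = nm, curves[[nm]])))
    write_tsv(tab, file.path(config$out_dir, "ltt.tsv"))
    bundle$ltt <- curves
    bundle$timings$ltt <- tic() - t0
  }
  summary <- list(
    config = config[setdiff(names(config), "out_dir")],
    config_hash = bundle$config_hash, seed = config$seed,
    timings = bundle$timings,
    bisse = if (!is.null(bundle$bisse)) list(
      models = bundle$bisse$comparison$models,
      lrt = bundle$bisse$comparison$lrt),
    medusa = if (!is.null(bundle$medusa)) list(
      n_shifts = length(bundle$medusa$model$shift_edges),
      AICc = bundle$medusa$model$AICc,
      regimes = bundle$medusa$model$regimes),
    sisters = if (!is.null(bundle$sisters) &&
                  is.null(bundle$sisters$error)) list(
      n_pairs = nrow(bundle$sisters$pairs),
      p_two_sided = bundle$sisters$test$p_two_sided,
      p_greater = bundle$sisters$test$p_greater))
  jsonlite::write_json(summary, file.path(config$out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       dataframe = "rows")
  invisible(bundle)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
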