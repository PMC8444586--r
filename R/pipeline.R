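#' Build a pipeline run configuration
#'
#' A run configuration collects every parameter of the four pipeline stages
#' (simulate, profile, differential, age) plus the master seed and output
#' directory. It round-trips losslessly through YAML
#' ([write_run_config()] / [read_run_config()]), and every seed used by a
#' stage is derived from `seed` and recorded in the run manifest.
#'
#' @param outdir output directory for all stage outputs and the manifest.
#' @param seed master integer seed.
#' @param stages character subset of
#'   `c("simulate", "profile", "differential", "age")`.
#' @param synthetic named list of [synthetic_config()] arguments (without
#'   `seed`).
#' @param inputs named list of input paths (`ko_table`, `metadata`,
#'   `hierarchy`) used when the simulate stage is disabled.
#' @param differential named list: `q_threshold`, `pseudocount`.
#' @param age named list: `R`, `n_trees`, `gamma`, `spline_df`, `alpha`,
#'   `feature_sets`, and optionally `n_per_timepoint` (omitted = minimum
#'   available per time point).
#' @return list of class `run_config`.
#' @export
run_config <- function(outdir = "metagage_run",
                       seed = 1,
                       stages = c("simulate", "profile", "differential", "age"),
                       synthetic = list(),
                       inputs = list(),
                       differential = list(q_threshold = 0.01,
                                           pseudocount = 1e-10),
                       age = list(R = 10, n_trees = 10000, gamma = 0.8,
                                  spline_df = 3, alpha = 0.05,
                                  feature_sets = "modules")) {
  stages <- match.arg(stages, several.ok = TRUE)
  cfg <- list(outdir = outdir, seed = as.integer(seed), stages = stages,
              synthetic = synthetic, inputs = inputs,
              differential = utils::modifyList(
                list(q_threshold = 0.01, pseudocount = 1e-10), differential),
              age = utils::modifyList(
                list(R = 10, n_trees = 10000, gamma = 0.8, spline_df = 3,
                     alpha = 0.05, feature_sets = "modules"), age))
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw[intersect(names(raw), names(formals(run_config)))])
}

#' Validate pipeline input files
#'
#' Checks feature-table and metadata TSVs for schema problems: duplicate
#' ids, negative or non-finite abundances, missing metadata columns, and
#' sample-id disagreement between tables and metadata. Never mutates
#' inputs.
#'
#' @param table_paths named character vector/list of feature-table TSV
#'   paths.
#' @param metadata_path metadata TSV path.
#' @return data.frame of issues (`file`, `check`, `detail`); zero rows when
#'   everything is clean.
#' @export
validate_inputs <- function(table_paths, metadata_path) {
  issues <- list()
  flag <- function(file, check, detail) {
    issues[[length(issues) + 1]] <<- data.frame(
      file = file, check = check, detail = detail, stringsAsFactors = FALSE)
  }
  meta <- NULL
  if (!file.exists(metadata_path)) {
    stop("metadata file not readable: ", metadata_path)
  }
  meta <- utils::read.delim(metadata_path, check.names = FALSE,
                            stringsAsFactors = FALSE)
  required <- c("sample_id", "subject_id", "age_months", "cohort")
  miss <- setdiff(required, names(meta))
  if (length(miss)) {
    flag(metadata_path, "missing_columns", paste(miss, collapse = ", "))
  }
  if ("sample_id" %in% names(meta) && anyDuplicated(meta$sample_id)) {
    flag(metadata_path, "duplicate_sample_ids",
         paste(unique(meta$sample_id[duplicated(meta$sample_id)]),
               collapse = ", "))
  }
  for (nm in names(table_paths)) {
    path <- table_paths[[nm]]
    if (!file.exists(path)) stop("table file not readable: ", path)
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (!"feature_id" %in% names(df)) {
      flag(path, "missing_feature_id_column", "no 'feature_id' column")
      next
    }
    if (anyDuplicated(df$feature_id)) {
      flag(path, "duplicate_feature_ids",
           paste(unique(df$feature_id[duplicated(df$feature_id)]),
                 collapse = ", "))
    }
    m <- as.matrix(df[, setdiff(names(df), "feature_id"), drop = FALSE])
    if (any(!is.finite(m))) flag(path, "nonfinite_abundance", "NA/Inf values")
    if (any(m < 0, na.rm = TRUE)) {
      flag(path, "negative_abundance",
           sprintf("%d negative cells", sum(m < 0, na.rm = TRUE)))
    }
    if ("sample_id" %in% names(meta)) {
      extra <- setdiff(colnames(m), meta$sample_id)
      if (length(extra)) {
        flag(path, "samples_not_in_metadata", paste(extra, collapse = ", "))
      }
    }
  }
  if (length(issues)) do.call(rbind, issues) else {
    data.frame(file = character(0), check = character(0),
               detail = character(0), stringsAsFactors = FALSE)
  }
}

#' @noRd
stage_key <- function(params, input_files) {
  blob <- jsonlite::toJSON(params, auto_unbox = TRUE, digits = NA,
                           null = "null")
  hashes <- if (length(input_files)) {
    unname(tools::md5sum(input_files))
  } else character(0)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(c(as.character(blob), hashes), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full pipeline from a configuration
#'
#' Executes the enabled stages in dependency order
#' (simulate -> profile -> differential -> age), writing every output as
#' TSV under `config$outdir` and a JSON manifest recording the package
#' version, the configuration, every derived seed, and the MD5 hash of
#' every output. A stage whose parameters and inputs are unchanged since a
#' previous run in the same directory (content-hash check) is skipped and
#' its outputs reused.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @return invisibly, the manifest list (also written to
#'   `outdir/manifest.json`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[metagage] ", sprintf(...))
  out <- function(f) file.path(outdir, f)

  manifest_path <- out("manifest.json")
  prev <- if (file.exists(manifest_path)) {
    try(jsonlite::read_json(manifest_path), silent = TRUE)
  } else NULL
  if (inherits(prev, "try-error")) prev <- NULL
  manifest <- list(package = "metagage",
                   version = as.character(utils::packageVersion("metagage")),
                   seed = config$seed, stages = list())
  stage_seeds <- derive_seeds(config$seed, 4)
  names(stage_seeds) <- c("simulate", "profile", "differential", "age")

  fresh <- function(stage, key, outputs) {
    pk <- prev$stages[[stage]]$key
    if (!is.null(pk) && identical(pk, key) &&
        all(file.exists(file.path(outdir, outputs)))) {
      say("%s: inputs unchanged, reusing previous outputs", stage)
      FALSE
    } else TRUE
  }
  record <- function(stage, key, outputs, seed = NULL) {
    manifest$stages[[stage]] <<- list(
      key = key, outputs = outputs, seed = seed,
      md5 = as.list(tools::md5sum(file.path(outdir, outputs))))
  }

  # --- simulate ------------------------------------------------------------
  sim_files <- c("ko_abundance.tsv", "metadata.tsv", "ground_truth.tsv",
                 "hierarchy.tsv")
  if ("simulate" %in% config$stages) {
    sc <- do.call(synthetic_config,
                  c(config$synthetic, list(seed = stage_seeds[["simulate"]])))
    key <- stage_key(list(stage = "simulate", config = config$synthetic,
                          seed = stage_seeds[["simulate"]]), character(0))
    if (fresh("simulate", key, sim_files)) {
      say("simulate: %d features, %d subjects/cohort, delay %.1f months",
          sc$n_features_ko, sc$n_subjects_per_cohort, sc$delay_months)
      sim <- generate_profiles(sc)
      hier_map <- synthetic_hierarchy(sc)
      write_feature_table(sim$table, out("ko_abundance.tsv"))
      write_metadata(sim$metadata, out("metadata.tsv"))
      utils::write.table(sim$truth, out("ground_truth.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(hier_map, out("hierarchy.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    record("simulate", key, sim_files, stage_seeds[["simulate"]])
    ko_path <- out("ko_abundance.tsv")
    meta_path <- out("metadata.tsv")
    hier_path <- out("hierarchy.tsv")
  } else {
    ko_path <- config$inputs$ko_table
    meta_path <- config$inputs$metadata
    hier_path <- config$inputs$hierarchy
    if (is.null(ko_path) || is.null(meta_path) || is.null(hier_path)) {
      stop("with the simulate stage disabled, config$inputs must provide ",
           "ko_table, metadata and hierarchy paths")
    }
    for (p in c(ko_path, meta_path, hier_path)) {
      if (!file.exists(p)) stop("input file not found: ", p)
    }
  }

  # --- profile -------------------------------------------------------------
  prof_files <- c("module_abundance.tsv", "pathway_abundance.tsv")
  if ("profile" %in% config$stages) {
    key <- stage_key(list(stage = "profile"), c(ko_path, hier_path))
    if (fresh("profile", key, prof_files)) {
      ko <- read_feature_table(ko_path, "KO", normalized = TRUE)
      hier <- functional_hierarchy(utils::read.delim(hier_path,
                                                     stringsAsFactors = FALSE))
      say("profile: aggregating %d KOs to modules and pathways", nrow(ko$abundance))
      mods <- aggregate_support(ko, hier, "module")
      paths <- aggregate_support(ko, hier, "pathway")
      write_feature_table(mods, out("module_abundance.tsv"))
      write_feature_table(paths, out("pathway_abundance.tsv"))
    }
    record("profile", key, prof_files)
  }

  # --- differential --------------------------------------------------------
  diff_files <- c("differential_modules.tsv", "differential_pathways.tsv",
                  "patterns_modules.tsv", "patterns_pathways.tsv")
  if ("differential" %in% config$stages) {
    key <- stage_key(list(stage = "differential", config = config$differential),
                     c(file.path(outdir, prof_files), meta_path))
    if (fresh("differential", key, diff_files)) {
      meta <- read_metadata(meta_path)
      tps <- sort(unique(meta$age_months))
      for (lv in c("modules", "pathways")) {
        tab <- read_feature_table(out(paste0(sub("s$", "", lv), "_abundance.tsv")),
                                  level = sub("s$", "", lv), normalized = TRUE)
        res <- do.call(rbind, lapply(tps, function(t) {
          compare_cohorts(tab, meta, timepoint = t,
                          q_threshold = config$differential$q_threshold,
                          pseudocount = config$differential$pseudocount)
        }))
        pat <- classify_patterns(res)
        utils::write.table(res, out(paste0("differential_", lv, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(pat, out(paste0("patterns_", lv, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        say("differential (%s): %d/%d significant at q < %g across %d time points",
            lv, sum(res$direction != "ns"), nrow(res),
            config$differential$q_threshold, length(tps))
      }
    }
    record("differential", key, diff_files)
  }

  # --- age -----------------------------------------------------------------
  age_files <- c("age_performance.tsv", "relative_ages.tsv", "delay_tests.tsv")
  if ("age" %in% config$stages) {
    key <- stage_key(list(stage = "age", config = config$age,
                          seed = stage_seeds[["age"]]),
                     c(file.path(outdir, prof_files), meta_path))
    if (fresh("age", key, age_files)) {
      meta <- read_metadata(meta_path)
      mods <- read_feature_table(out("module_abundance.tsv"), "module", TRUE)
      paths <- read_feature_table(out("pathway_abundance.tsv"), "pathway", TRUE)
      say("age: %d replicates, %d trees, gamma %.2f, feature sets: %s",
          config$age$R, config$age$n_trees, config$age$gamma,
          paste(config$age$feature_sets, collapse = ", "))
      res <- run_age_analysis(
        modules = mods, pathways = paths, meta = meta,
        feature_sets = config$age$feature_sets,
        R = config$age$R, n_trees = config$age$n_trees,
        gamma = config$age$gamma, spline_df = config$age$spline_df,
        n_per_timepoint = config$age$n_per_timepoint,
        alpha = config$age$alpha,
        seed = stage_seeds[["age"]])
      collect <- function(getter) {
        do.call(rbind, unlist(lapply(names(res), function(fs) {
          lapply(names(res[[fs]]), function(co) {
            df <- getter(res[[fs]][[co]])
            cbind(feature_set = fs, train_cohort = co, df,
                  stringsAsFactors = FALSE)
          })
        }), recursive = FALSE))
      }
      utils::write.table(collect(function(b) b$performance),
                         out("age_performance.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(collect(function(b) b$estimates),
                         out("relative_ages.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(collect(function(b) b$delay$per_replicate),
                         out("delay_tests.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    record("age", key, age_files, stage_seeds[["age"]])
  }

  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  say("done; manifest at %s", manifest_path)
  invisible(manifest)
}
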