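# End-to-end pipeline: simulate (or load) a proteome, reduce redundancy,
# encode features, rank them, and cross-validate.  Stages write their
# artifacts under the output directory; a stage whose inputs and
# configuration are unchanged (md5-checksum gated) is skipped on re-run.

#' Default pipeline configuration
#'
#' @return A named list understood by [run_pipeline()]: `data_dir` (input
#'   proteome directory; `NULL` means simulate one), `out_dir`, `window`
#'   half-size `n`, feature `blocks`, RBFN `sigma` and `ridge`, CV folds
#'   `k`, identity `threshold` for redundancy reduction (`NULL` disables
#'   the reduction stage), `seed`, and `sim` (parameter overrides for
#'   [simulate_proteome()]).
#' @export
pipeline_config <- function() {
  list(data_dir = NULL, out_dir = "ubilys-run", n = 20L,
       blocks = c("AAC", "PSSM400"), sigma = 5, ridge = 1e-8, k = 5L,
       threshold = NULL, seed = 1L, sim = list())
}

.config_hash <- function(cfg) {
  cfg$out_dir <- NULL  # the hash reflects the analysis, not its location
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(cfg), tmp)
  unname(tools::md5sum(tmp))
}

.stage_state <- function(out_dir) {
  f <- file.path(out_dir, "state.json")
  if (file.exists(f)) jsonlite::read_json(f, simplifyVector = TRUE)
  else list()
}

.stage_fresh <- function(state, stage, key, outputs) {
  identical(state[[stage]], key) && all(file.exists(outputs))
}

#' Run the full pipeline
#'
#' Stages: `simulate` (skipped when `data_dir` points at an existing
#' proteome), `reduce` (skipped unless an identity `threshold` is set),
#' `featurize`, `fscore`, `crossval`.  Each stage logs to `stderr`, embeds
#' the seed and configuration hash in its outputs, and is skipped on
#' re-run when its inputs are unchanged.
#'
#' @param config List as from [pipeline_config()]; partial lists are
#'   filled with defaults.  May also be the path of a YAML file holding
#'   such a list.
#' @return Invisibly, a list with the output paths and the
#'   cross-validation result.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(pipeline_config(), config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  state <- .stage_state(cfg$out_dir)
  hash <- .config_hash(cfg)
  log <- function(...) message("[ubilys] ", ...)

  # -- stage: simulate / load ------------------------------------------
  data_dir <- cfg$data_dir
  if (is.null(data_dir)) {
    data_dir <- file.path(cfg$out_dir, "data")
    key <- paste0("sim:", hash)
    if (.stage_fresh(state, "simulate", key,
                     file.path(data_dir, "proteins.fasta"))) {
      log("simulate: up to date, skipped")
    } else {
      log("simulate: generating synthetic proteome")
      sim <- do.call(simulate_proteome,
                     c(cfg$sim, list(seed = cfg$seed)))
      write_proteome(sim, data_dir)
      state$simulate <- key
    }
  }
  if (!file.exists(file.path(data_dir, "proteins.fasta"))) {
    stop("stage simulate/load: no proteome at '", data_dir, "'")
  }
  data <- read_proteome(data_dir)
  input_md5 <- paste(unname(tools::md5sum(
    c(file.path(data_dir, "proteins.fasta"),
      file.path(data_dir, "sites.tsv")))), collapse = "")

  # -- stage: reduce ----------------------------------------------------
  frags <- extract_fragments(data$prot, data$sites, n = cfg$n)
  if (!is.null(cfg$threshold)) {
    log("reduce: collapsing redundant fragments at identity > ",
        cfg$threshold)
    frags <- reduce_fragments(frags, data$prot, cfg$threshold)
    log("reduce: kept ", nrow(frags), " fragments")
  }

  # -- stage: featurize -------------------------------------------------
  feat_file <- file.path(cfg$out_dir, "features.tsv")
  key <- paste0("feat:", hash, ":", input_md5)
  if (.stage_fresh(state, "featurize", key, feat_file)) {
    log("featurize: up to date, skipped")
    tab <- utils::read.table(feat_file, header = TRUE, sep = "\t",
                             check.names = FALSE)
    ds <- list(x = as.matrix(tab[, setdiff(colnames(tab), "label"),
                                 drop = FALSE]),
               labels = tab$label)
  } else {
    log("featurize: encoding blocks ", paste(cfg$blocks, collapse = "+"))
    ds <- encode_dataset(frags, data$prot, data$profiles,
                         blocks = cfg$blocks)
    tab <- as.data.frame(ds$x, check.names = FALSE)
    tab$label <- ds$labels
    utils::write.table(tab, feat_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    state$featurize <- key
  }

  # -- stage: fscore ----------------------------------------------------
  fs_file <- file.path(cfg$out_dir, "fscores.tsv")
  key <- paste0("fscore:", hash, ":", input_md5)
  if (.stage_fresh(state, "fscore", key, fs_file)) {
    log("fscore: up to date, skipped")
  } else {
    log("fscore: ranking ", ncol(ds$x), " features")
    ranks <- rank_features(ds$x, ds$labels)
    utils::write.table(ranks, fs_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    state$fscore <- key
  }

  # -- stage: crossval --------------------------------------------------
  cv_file <- file.path(cfg$out_dir, "cv.json")
  key <- paste0("cv:", hash, ":", input_md5)
  if (.stage_fresh(state, "crossval", key, cv_file)) {
    log("crossval: up to date, skipped")
    cv <- jsonlite::read_json(cv_file, simplifyVector = TRUE)
  } else {
    log("crossval: ", cfg$k, "-fold cross-validation")
    res <- kfold_cv(ds$x, ds$labels, k = cfg$k, seed = cfg$seed,
                    sigma = cfg$sigma, ridge = cfg$ridge)
    cv <- list(seed = cfg$seed, config_hash = hash, k = cfg$k,
               fold_counts = res$fold_counts,
               pooled_counts = as.list(res$pooled_counts),
               metrics = as.list(res$metrics))
    jsonlite::write_json(cv, cv_file, digits = NA, auto_unbox = TRUE,
                         pretty = TRUE)
    state$crossval <- key
  }

  jsonlite::write_json(state, file.path(cfg$out_dir, "state.json"),
                       auto_unbox = TRUE)
  invisible(list(out_dir = cfg$out_dir, features = feat_file,
                 fscores = fs_file, cv_file = cv_file, cv = cv))
}
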