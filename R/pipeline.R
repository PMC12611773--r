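## Pipeline plumbing: one JSON config can describe every stage; each stage
## reads its inputs from disk, writes TSV outputs plus a JSON manifest
## (input hashes, seed, package version) so any stage can be rerun exactly.

STAGES <- c("simulate", "fit-uncertainty", "fit-transform", "sample",
            "pseudolabel", "distill", "evaluate")

require_field <- function(cfg, field, where = "config") {
  parts <- strsplit(field, ".", fixed = TRUE)[[1L]]
  node <- cfg
  for (p in parts) {
    if (!is.list(node) || is.null(node[[p]]))
      stopf("%s is missing required field `%s`", where, field)
    node <- node[[p]]
  }
  node
}

read_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stopf("config must be a JSON object")
  config
}

write_manifest <- function(out_dir, stage, cfg, inputs, outputs) {
  hashes <- if (length(inputs)) as.list(tools::md5sum(unlist(inputs))) else list()
  manifest <- list(
    stage = stage,
    seed = cfg$seed %||% 1L,
    package_version = as.character(utils::packageVersion("alignsim")),
    input_md5 = hashes,
    outputs = as.list(unlist(outputs)),
    stage_params = cfg$stage_params %||% list()
  )
  jsonlite::write_json(manifest, file.path(out_dir, paste0(stage, "_manifest.json")),
                       auto_unbox = TRUE, digits = NA)
}

#' Run one pipeline stage from a JSON configuration
#'
#' Stages: `simulate` (hierarchy + annotator responses),
#' `fit-uncertainty` (variational embedding from responses),
#' `fit-transform` (affine transform from teacher matrix + soft targets),
#' `sample` (triplet sampling over a representation matrix),
#' `pseudolabel` (teacher soft/hard labels for sampled triplets),
#' `distill` (student fine-tuning) and `evaluate` (alignment report).
#' Inputs are read from paths in the config; outputs are TSV/JSON files
#' under `out_dir` together with a manifest recording input hashes, the
#' seed and the package version.  Inputs are never mutated.
#'
#' @param config path to a JSON config file or an equivalent list.  Top
#'   level: `stage`, `seed`, `out_dir`, `paths` (stage inputs) and
#'   `stage_params` (stage tuning parameters).
#' @return invisible named list of written artifact paths.
#' @export
run_stage <- function(config) {
  cfg <- read_config(config)
  stage <- require_field(cfg, "stage")
  if (!stage %in% STAGES)
    stopf("unknown stage `%s`; expected one of: %s", stage,
          paste(STAGES, collapse = ", "))
  out_dir <- require_field(cfg, "out_dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(cfg$seed %||% 1L)
  sp <- cfg$stage_params %||% list()
  inputs <- character(0)
  outputs <- list()

  if (stage == "simulate") {
    space <- generate_hierarchy(
      n_super = sp$n_super %||% 3L,
      n_basic_per_super = sp$n_basic_per_super %||% 3L,
      n_items_per_basic = sp$n_items_per_basic %||% 5L,
      dim = sp$dim %||% 8L,
      level_spreads = sp$level_spreads %||% c(6, 1.5, 0.4),
      seed = seed)
    annot <- annotator_model(
      temperature = sp$temperature %||% 1,
      lapse_rate = sp$lapse_rate %||% 0.1,
      rt_intercept = sp$rt_intercept %||% 0.5,
      rt_slope = sp$rt_slope %||% 1,
      rt_noise_sd = sp$rt_noise_sd %||% 0.1)
    trips <- sample_random_triplets(nrow(space$embeddings),
                                    sp$n_triplets %||% 500L,
                                    seed = derive_seed(seed, 2L))
    resp <- simulate_responses(space, trips, annot,
                               sp$n_annotators_per_triplet %||% 5L,
                               seed = derive_seed(seed, 3L))
    outputs$embeddings <- file.path(out_dir, "ground_truth_embeddings.tsv")
    outputs$labels <- file.path(out_dir, "ground_truth_labels.tsv")
    outputs$responses <- file.path(out_dir, "responses.tsv")
    write_matrix(space$embeddings, outputs$embeddings)
    write_labels(space$labels, outputs$labels)
    write_responses(resp, outputs$responses)
  } else if (stage == "fit-uncertainty") {
    path <- require_field(cfg, "paths.responses")
    inputs <- path
    resp <- read_responses(path)
    ve <- fit_uncertainty_model(
      resp, d = sp$d %||% 8L,
      epochs = sp$epochs %||% 80L,
      learning_rate = sp$learning_rate %||% 0.05,
      batch_size = sp$batch_size %||% 128L,
      prior_weight = sp$prior_weight %||% 1e-3,
      seed = seed)
    prefix <- file.path(out_dir, "uncertainty_model")
    write_variational_embedding(ve, prefix)
    soft <- mc_triplet_probabilities(ve, resp$triplets,
                                     n_samples = sp$mc_samples %||% 50L,
                                     seed = derive_seed(seed, 4L))
    if (is.null(dim(soft))) soft <- matrix(soft, nrow = 1L)
    outputs$soft_targets <- file.path(out_dir, "soft_targets.tsv")
    write_triplets(resp$triplets, outputs$soft_targets,
                   choice = argmax3(soft), soft = soft)
    outputs$model_prefix <- prefix
  } else if (stage == "fit-transform") {
    x_path <- require_field(cfg, "paths.teacher_embeddings")
    t_path <- require_field(cfg, "paths.soft_targets")
    inputs <- c(x_path, t_path)
    X <- read_matrix(x_path)
    tt <- read_triplets(t_path)
    if (is.null(tt$soft)) stopf("`%s` carries no soft targets", t_path)
    resp <- triplet_responses(tt$triplets, choice = tt$choice, soft = tt$soft)
    tr <- fit_transform(X, resp,
                        lambda_reg = sp$lambda_reg %||% 0.01,
                        learning_rate = sp$learning_rate %||% 0.01,
                        epochs = sp$epochs %||% 60L,
                        batch_size = sp$batch_size %||% 256L,
                        seed = seed)
    prefix <- file.path(out_dir, "transform")
    write_transform(tr, prefix)
    outputs$transform_prefix <- prefix
  } else if (stage == "sample") {
    z_path <- require_field(cfg, "paths.representations")
    inputs <- z_path
    Z <- read_matrix(z_path)
    strategy <- sp$strategy %||% "cluster_boundary"
    n <- sp$n_triplets %||% 1000L
    trips <- switch(
      strategy,
      random = sample_random_triplets(nrow(Z), n, seed = seed),
      cluster_boundary = {
        cands <- sp$candidate_cs %||% c(2L, 3L, 4L, 5L, 6L, 8L)
        c_use <- sp$c %||% as.integer(select_k_elbow(Z, cands, seed = seed))
        assign <- cluster_representations(Z, c_use,
                                          seed = derive_seed(seed, 2L))
        sample_cluster_boundary_triplets(assign, n,
                                         seed = derive_seed(seed, 3L))
      },
      stopf("unknown sampling strategy `%s`", strategy))
    outputs$triplets <- file.path(out_dir, "sampled_triplets.tsv")
    write_triplets(trips, outputs$triplets)
  } else if (stage == "pseudolabel") {
    z_path <- require_field(cfg, "paths.representations")
    t_path <- require_field(cfg, "paths.triplets")
    tr_prefix <- cfg$paths$transform_prefix
    inputs <- c(z_path, t_path)
    Z <- read_matrix(z_path)
    if (!is.null(tr_prefix)) Z <- apply_transform(read_transform(tr_prefix), Z)
    trips <- read_triplets(t_path)$triplets
    ds <- pseudolabel(Z, trips, temperature = sp$temperature %||% 1)
    outputs$dataset <- file.path(out_dir, "pseudolabelled_triplets.tsv")
    write_triplets(ds$triplets, outputs$dataset, choice = ds$choice,
                   soft = ds$soft)
  } else if (stage == "distill") {
    d_path <- require_field(cfg, "paths.dataset")
    f_path <- require_field(cfg, "paths.features")
    inputs <- c(d_path, f_path)
    tt <- read_triplets(d_path)
    if (is.null(tt$soft)) stopf("`%s` carries no soft labels", d_path)
    data <- triplet_responses(tt$triplets, choice = tt$choice, soft = tt$soft)
    Feat <- read_matrix(f_path)
    student <- student_encoder(sp$encoder %||% "linear",
                               in_dim = ncol(Feat),
                               out_dim = sp$out_dim %||% 8L,
                               hidden = sp$hidden %||% 32L,
                               seed = derive_seed(seed, 5L))
    tuned <- distill(student, data, Feat,
                     tau_student = sp$tau_student %||% 1,
                     lambda_wd = sp$lambda_wd %||% 0,
                     learning_rate = sp$learning_rate %||% 0.01,
                     epochs = sp$epochs %||% 40L,
                     batch_size = sp$batch_size %||% 256L,
                     seed = seed)
    outputs$student <- file.path(out_dir, "student_representations.tsv")
    write_matrix(encode(tuned, Feat), outputs$student)
    outputs$log <- file.path(out_dir, "distill_log.json")
    jsonlite::write_json(list(history = attr(tuned, "history"),
                              config = attr(tuned, "config")),
                         outputs$log, auto_unbox = TRUE, digits = NA)
  } else if (stage == "evaluate") {
    m_path <- require_field(cfg, "paths.model_embeddings")
    r_path <- require_field(cfg, "paths.responses")
    inputs <- c(m_path, r_path)
    X <- read_matrix(m_path)
    resp <- read_responses(r_path)
    trips <- resp$triplets
    s <- pair_similarities(X, trips)
    if (is.null(dim(s))) s <- matrix(s, nrow = 1L)
    model_pair <- choose_odd_one_out(s)$pair
    trip_f <- factor(resp$triplet, levels = seq_len(nrow(trips)))
    counts <- t(vapply(split(resp$choice, trip_f),
                       function(ch) tabulate(ch, 3L), numeric(3)))
    answered <- rowSums(counts) > 0
    maj <- rep(NA_integer_, nrow(counts))
    maj[answered] <- vapply(which(answered), function(i)
      majority_response(counts[i, ], seed = derive_seed(seed, i)),
      numeric(1))
    acc <- odd_one_out_accuracy(model_pair[answered], maj[answered])
    ceiling <- noise_ceiling_loo(resp, seed = derive_seed(seed, 11L))
    ent <- triplet_entropy(choice_probabilities(s, sp$temperature %||% 1))
    report <- list(n_triplets = nrow(trips),
                   odd_one_out_accuracy = acc,
                   noise_ceiling_loo = ceiling,
                   seed = seed)
    if (!is.null(resp$rt_seconds)) {
      pre <- preprocess_rts(resp$rt_seconds)
      keep <- pre$keep
      mlrt <- tapply(pre$log_rt[keep], trip_f[keep], mean)
      ok <- which(!is.na(mlrt))
      report$entropy_rt_spearman <-
        entropy_rt_correlation(ent[ok], as.numeric(mlrt[ok]))
    }
    ci <- bootstrap_ci(as.numeric(model_pair[answered] == maj[answered]),
                       n_boot = sp$n_boot %||% 100L,
                       sample_size = sp$boot_sample_size %||% 1000L,
                       seed = derive_seed(seed, 12L))
    report$accuracy_ci <- ci
    outputs$report <- file.path(out_dir, "evaluation_report.json")
    jsonlite::write_json(report, outputs$report, auto_unbox = TRUE,
                         digits = NA)
    summary_tsv <- file.path(out_dir, "evaluation_summary.tsv")
    utils::write.table(
      data.frame(metric = c("odd_one_out_accuracy", "noise_ceiling_loo"),
                 value = c(acc, ceiling)),
      summary_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs$summary <- summary_tsv
  }

  write_manifest(out_dir, stage, cfg, inputs, outputs)
  invisible(outputs)
}

#' Run the full desk-scale pipeline end to end
#'
#' Convenience wrapper chaining simulate -> fit-uncertainty ->
#' fit-transform -> sample -> pseudolabel -> distill -> evaluate in one
#' output directory, with per-stage overrides taken from
#' `config$stages$<stage>`.
#'
#' @param out_dir output directory.
#' @param seed integer seed.
#' @param config optional list of per-stage `stage_params` overrides.
#' @return invisible list of per-stage artifact paths.
#' @export
run_pipeline <- function(out_dir, seed = 1L, config = list()) {
  ov <- function(stage) config$stages[[stage]] %||% list()
  arts <- list()
  arts$simulate <- run_stage(list(
    stage = "simulate", out_dir = out_dir, seed = seed,
    stage_params = ov("simulate")))
  arts$fit_uncertainty <- run_stage(list(
    stage = "fit-uncertainty", out_dir = out_dir, seed = seed,
    paths = list(responses = arts$simulate$responses),
    stage_params = ov("fit-uncertainty")))
  arts$fit_transform <- run_stage(list(
    stage = "fit-transform", out_dir = out_dir, seed = seed,
    paths = list(teacher_embeddings = arts$simulate$embeddings,
                 soft_targets = arts$fit_uncertainty$soft_targets),
    stage_params = ov("fit-transform")))
  arts$sample <- run_stage(list(
    stage = "sample", out_dir = out_dir, seed = seed,
    paths = list(representations = arts$simulate$embeddings),
    stage_params = ov("sample")))
  arts$pseudolabel <- run_stage(list(
    stage = "pseudolabel", out_dir = out_dir, seed = seed,
    paths = list(representations = arts$simulate$embeddings,
                 triplets = arts$sample$triplets,
                 transform_prefix = arts$fit_transform$transform_prefix),
    stage_params = ov("pseudolabel")))
  ## desk-scale student features: the ground-truth embeddings themselves
  arts$distill <- run_stage(list(
    stage = "distill", out_dir = out_dir, seed = seed,
    paths = list(dataset = arts$pseudolabel$dataset,
                 features = arts$simulate$embeddings),
    stage_params = ov("distill")))
  arts$evaluate <- run_stage(list(
    stage = "evaluate", out_dir = out_dir, seed = seed,
    paths = list(model_embeddings = arts$distill$student,
                 responses = arts$simulate$responses),
    stage_params = ov("evaluate")))
  invisible(arts)
}
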