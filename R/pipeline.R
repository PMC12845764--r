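# End-to-end pipeline plumbing: config validation, staged execution with
# hash-based skipping, and run manifests.

PIPELINE_STAGES <- c("preprocess", "train_gan", "generate", "refine",
                     "evaluate", "compare")

#' Default pipeline configuration
#'
#' The fully resolved default run configuration, as a nested list mirroring
#' each stage's config type. [validate_config] fills these defaults into a
#' user config and rejects unknown keys and out-of-range values.
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    out_dir = "mcwavegan_run",
    target_class = "QueenPresent",
    fixtures = list(n_per_class = 10L, rate = 32000, duration = 10,
                    noise_snr_db = 10),
    preprocess = list(target_rate = 16384, band_low = 20, band_high = 2000,
                      segment_len = 16384L, silence_floor_db = -40,
                      min_tail_fraction = 0.25),
    gan = list(preset = "desk", model_size = NULL, output_len = 16384L,
               iterations = NULL, batch_size = 64L, latent_dim = 100L,
               phase_shuffle_n = 2L, n_critic = 5L, gp_lambda = 10,
               checkpoint_every = 1000L),
    generate = list(n_clips = 500L),
    refine = list(betas = c(0.01, 0.5, 0.9), n_out = 500L, ema_alpha = 0.2),
    features = list(n_bands = 16L, frame_len = 1024L, hop = 512L,
                    mfcc_n = 20L),
    compare = list(n_pairs = 3L, n_bins = 50L)
  )
}

#' Validate and resolve a pipeline configuration
#'
#' Parses a YAML document (text, file path, or an already-parsed list),
#' fills in defaults, rejects unknown keys, and checks ranges — in
#' particular the balance parameter must satisfy `0 <= beta <= 1`.
#'
#' @param raw YAML text, a file path, a list, or `NULL` (all defaults).
#' @return The resolved configuration list, classed `run_config`.
#' @export
validate_config <- function(raw = NULL) {
  user <- if (is.null(raw)) list()
    else if (is.list(raw)) raw
    else if (length(raw) == 1L && file.exists(raw)) yaml::read_yaml(raw)
    else yaml::yaml.load(paste(raw, collapse = "\n"))
  if (is.null(user)) user <- list()
  def <- default_config()
  merged <- merge_config(def, user, path = "")
  betas <- merged$refine$betas
  if (any(betas < 0 | betas > 1))
    stopf("refine beta = %g violates the bound 0 <= beta <= 1",
          betas[which(betas < 0 | betas > 1)[1]])
  if (merged$refine$ema_alpha <= 0 || merged$refine$ema_alpha > 1)
    stopf("ema_alpha must lie in (0, 1]")
  structure(merged, class = "run_config")
}

#' @keywords internal
merge_config <- function(def, user, path) {
  unknown <- setdiff(names(user), names(def))
  if (length(unknown))
    stopf("unknown config key%s: %s",
          if (length(unknown) > 1) "s" else "",
          paste0(sub("^\\.", "", paste0(path, ".", unknown)), collapse = ", "))
  for (nm in names(user)) {
    def[[nm]] <- if (is.list(def[[nm]]) && is.list(user[[nm]]))
      merge_config(def[[nm]], user[[nm]], paste0(path, ".", nm))
    else user[[nm]]
  }
  def
}

#' @keywords internal
config_hash <- function(x) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(x, tf)
  unname(tools::md5sum(tf))
}

#' @keywords internal
files_hash <- function(paths) {
  paths <- sort(paths[file.exists(paths)])
  if (!length(paths)) return("none")
  h <- tools::md5sum(paths)
  config_hash(as.list(unname(h)))
}

# Write a stage manifest atomically (temp file + rename).
#' @keywords internal
write_manifest <- function(dir, manifest) {
  tf <- tempfile(tmpdir = dir)
  yaml::write_yaml(manifest, tf)
  file.rename(tf, file.path(dir, "manifest.yaml"))
  manifest
}

#' @keywords internal
stage_up_to_date <- function(dir, key) {
  mf <- file.path(dir, "manifest.yaml")
  if (!file.exists(mf)) return(FALSE)
  man <- tryCatch(yaml::read_yaml(mf), error = function(e) NULL)
  !is.null(man) && identical(man$key, key) &&
    all(file.exists(file.path(dir, man$outputs %||% character(0))))
}

#' Run the full pipeline
#'
#' Executes the six stages — preprocess (fixture generation plus
#' standardization), GAN training on the target class, generation of the
#' synthetic pool, Markov-chain refinement with a beta sweep, classifier
#' evaluation (class-distribution tables per beta), and the distributional
#' comparison — writing each stage's outputs and a manifest under
#' `cfg$out_dir/<stage>/`. A stage whose manifest already matches the
#' current config and input hashes is skipped; a stage failure halts the
#' run with the stage named, keeping earlier outputs.
#'
#' @param cfg a [validate_config] result (or anything it accepts).
#' @param verbose print one line per stage.
#' @return The run manifest: a list with one entry per stage (`status`
#'   `"done"` or `"skipped"`, timestamps, outputs), invisibly classed
#'   `run_manifest`.
#' @export
run_pipeline <- function(cfg = NULL, verbose = TRUE) {
  cfg <- validate_config(cfg)
  root <- cfg$out_dir
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(cfg), file.path(root, "config_resolved.yaml"))
  manifest <- list()

  run_stage <- function(name, inputs, action) {
    dir <- file.path(root, name)
    dir.create(dir, showWarnings = FALSE)
    key <- paste(config_hash(unclass(cfg)), files_hash(inputs), sep = "+")
    if (stage_up_to_date(dir, key)) {
      if (verbose) message(sprintf("[pipeline] %s: skipped (up to date)", name))
      man <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
      man$status <- "skipped"
      return(man)
    }
    t0 <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
    outputs <- tryCatch(action(dir), error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    man <- list(stage = name, key = key, seed = cfg$seed,
                version = as.character(utils::packageVersion("mcwavegan")),
                started = t0,
                finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                outputs = outputs, status = "done")
    write_manifest(dir, man)
    if (verbose) message(sprintf("[pipeline] %s: done", name))
    man
  }

  pre_cfg <- do.call(preprocess_config, cfg$preprocess)

  manifest$preprocess <- run_stage("preprocess", character(0), function(dir) {
    fx <- fixture_config(rate = cfg$fixtures$rate,
                         duration = cfg$fixtures$duration,
                         noise_snr_db = cfg$fixtures$noise_snr_db)
    segs <- gen_dataset(cfg$fixtures$n_per_class, fx,
                        seed = derive_seed(cfg$seed, "fixtures"), pre = pre_cfg)
    write_segment_set(segs, file.path(dir, "segments"))
    "segments/manifest.csv"
  })

  # lazy readers: each stage loads its inputs inside its own action, so a
  # corrupted intermediate surfaces as that stage's failure
  seg_dir <- file.path(root, "preprocess", "segments")
  read_segs <- function() read_segment_set(seg_dir)
  read_pool <- function() read_segment_set(file.path(root, "generate", "pool"))
  read_refined <- function() read_segment_set(file.path(root, "refine",
                                                        "refined"))
  feat_cfg <- do.call(feature_config, cfg$features)
  ref_model_cache <- NULL
  ref_model <- function() {
    if (is.null(ref_model_cache))
      ref_model_cache <<- lda_svm(read_segs(), feat_cfg)
    ref_model_cache
  }

  manifest$train_gan <- run_stage("train_gan",
                                  file.path(seg_dir, "manifest.csv"),
                                  function(dir) {
    segs <- read_segs()
    gc_args <- cfg$gan[!vapply(cfg$gan, is.null, TRUE)]
    gan_cfg <- do.call(gan_config, c(gc_args,
                                     list(seed = derive_seed(cfg$seed, "gan"))))
    target <- segs[segs$labels == cfg$target_class]
    if (nrow(target$segments) != gan_cfg$output_len)
      stopf("segment length %d != gan output_len %d; set preprocess$segment_len accordingly",
            nrow(target$segments), gan_cfg$output_len)
    model <- wavegan_train(target, gan_cfg)
    saveRDS(model, file.path(dir, "wavegan.rds"))
    utils::write.csv(model$trace, file.path(dir, "trace.csv"),
                     row.names = FALSE)
    c("wavegan.rds", "trace.csv")
  })

  manifest$generate <- run_stage("generate",
                                 file.path(root, "train_gan", "wavegan.rds"),
                                 function(dir) {
    model <- readRDS(file.path(root, "train_gan", "wavegan.rds"))
    pool <- wavegan_generate(model, cfg$generate$n_clips,
                             seed = derive_seed(cfg$seed, "generate"))
    write_segment_set(pool, file.path(dir, "pool"))
    "pool/manifest.csv"
  })

  manifest$refine <- run_stage("refine",
                               file.path(root, "generate", "pool",
                                         "manifest.csv"),
                               function(dir) {
    pool <- read_pool()
    segs <- read_segs()
    reals <- segs[segs$labels == cfg$target_class]
    rcfg <- refine_config(beta = cfg$refine$betas[1], n_out = cfg$refine$n_out,
                          ema_alpha = cfg$refine$ema_alpha,
                          seed = derive_seed(cfg$seed, "refine"))
    sw <- sweep_beta(pool, reals, cfg$refine$betas, rcfg, ref_model(),
                     target_label = cfg$target_class,
                     feature_cfg = feat_cfg)
    utils::write.csv(sw$table, file.path(dir, "beta_sweep.csv"),
                     row.names = FALSE)
    best <- sw$refined[[which(cfg$refine$betas == sw$beta_opt)[1]]]
    write_segment_set(best$clips, file.path(dir, "refined"))
    yaml::write_yaml(list(beta_opt = sw$beta_opt), file.path(dir, "beta_opt.yaml"))
    c("beta_sweep.csv", "refined/manifest.csv", "beta_opt.yaml")
  })

  manifest$evaluate <- run_stage("evaluate",
                                 file.path(root, "refine", "refined",
                                           "manifest.csv"),
                                 function(dir) {
    for (nm in c("pool", "refined")) {
      set <- if (nm == "pool") read_pool() else read_refined()
      m <- ref_model()
      dist <- class_distribution(predict(m, set), m$classes)
      utils::write.csv(dist, file.path(dir, paste0(nm, "_distribution.csv")),
                       row.names = FALSE)
    }
    c("pool_distribution.csv", "refined_distribution.csv")
  })

  manifest$compare <- run_stage("compare",
                                file.path(root, "refine", "refined",
                                          "manifest.csv"),
                                function(dir) {
    segs <- read_segs()
    reals <- segs[segs$labels == cfg$target_class]
    pool <- read_pool()
    refined <- read_refined()
    rep <- compare_report(reals, pool, refined, n_pairs = cfg$compare$n_pairs,
                          n_bins = cfg$compare$n_bins,
                          seed = derive_seed(cfg$seed, "compare"),
                          frame_len = min(cfg$features$frame_len,
                                          nrow(reals$segments)),
                          hop = cfg$features$hop)
    tab <- do.call(rbind, lapply(names(rep$pooled), function(kind)
      data.frame(kind = kind, js_gan = rep$pooled[[kind]]$js_gan,
                 js_refined = rep$pooled[[kind]]$js_refined,
                 improved = rep$pooled[[kind]]$improved)))
    utils::write.csv(tab, file.path(dir, "divergences.csv"),
                     row.names = FALSE)
    proj <- lda_projection(ref_model(), list(real = reals, gan = pool,
                                           refined = refined))
    utils::write.csv(proj$coords, file.path(dir, "lda_coords.csv"),
                     row.names = FALSE)
    c("divergences.csv", "lda_coords.csv")
  })

  class(manifest) <- "run_manifest"
  invisible(manifest)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest>\n")
  for (nm in names(x))
    cat(sprintf("  %-10s %s\n", nm, x[[nm]]$status))
  invisible(x)
}
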