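#' Pipeline configuration defaults
#'
#' All thresholds and hyperparameters in one nested list; every default is
#' the protocol value. Any element can be overridden via `...` using
#' `section.name` keys, e.g. `bp_config("quality.flat_tol" = 1e-6)`.
#'
#' @param ... named overrides (`"section.key" = value`).
#' @return Nested configuration list.
#' @export
bp_config <- function(...) {
  cfg <- list(
    fs = 125,
    selection = list(min_duration = 900, rest = 600, retry_step = 60,
                     seg_len = 15, gap = 300, age_range = c(18, 89)),
    quality = list(flat_min_len = 0.2, flat_tol = 0, sat_min_run = 3L,
                   ppg_band = c(0.5, 8), filter_order = 4,
                   duration_range = c(0.5, 1.5), count_range = c(10L, 30L),
                   min_pulse_pressure = 10, min_skewness = 0),
    morphology = list(band_sd = 1.25, max_abp = 180, max_duration = 1.2,
                      min_skewness = 0.2, cap = 10L),
    features = list(input_band = c(0.5, 45), sg_window = 7L, sg_degree = 3L,
                    window_s = 5, pad_steps = 15L),
    model = list(enc_units = c(4L, 20L, 100L), dec_units = c(8L, 40L, 200L)),
    training = list(lr = 1e-3, lambda = 0.01, batch_size = 48L,
                    patience_decay = 25L, patience_stop = 50L,
                    epochs = 100L),
    scenario = list(n_folds = 5L)
  )
  dots <- list(...)
  for (key in names(dots)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (length(parts) == 1L) cfg[[parts]] <- dots[[key]]
    else cfg[[parts[1]]][[parts[2]]] <- dots[[key]]
  }
  cfg
}

#' Process one record through selection, quality and morphology
#'
#' Runs the segment acceptance loop (first proposal after the 10-min rest
#' interval, one-minute retreats on rejection), and for an accepted pair
#' computes the average-pulse morphology of each 15-s segment, keeping the
#' raw segments and per-pulse arrays alongside.
#'
#' @param record a `bp_record`.
#' @param config a [bp_config()].
#' @return A container list with `record_id`, `subject_id`,
#'   `demographics`, `accepted`, `attempts` and, when accepted, `segments`
#'   (two entries with `raw_abp`, `raw_ppg`, `pulses`, `morphology`,
#'   `start`), or `NULL`-segments on exclusion.
#' @export
process_record <- function(record, config = bp_config()) {
  fs <- config$fs
  qfn <- function(pair) {
    for (seg in list(pair$seg_a, pair$seg_b)) {
      chk <- check_segment(seg$abp, seg$ppg, fs, config$quality)
      if (!chk$verdict$accepted) return(chk$verdict)
    }
    TRUE
  }
  res <- acceptance_loop(record, qfn, rest = config$selection$rest,
                         retry_step = config$selection$retry_step,
                         seg_len = config$selection$seg_len,
                         gap = config$selection$gap)
  base <- list(record_id = record$record_id, subject_id = record$subject_id,
               demographics = list(age = record$age, gender = record$gender),
               accepted = res$accepted, attempts = res$attempts)
  if (!res$accepted) return(c(base, list(segments = NULL, detail = res$detail)))
  segments <- purrr::imap(list(a = res$pair$seg_a, b = res$pair$seg_b),
    function(seg, nm) {
      chk <- check_segment(seg$abp, seg$ppg, fs, config$quality)
      morph <- compute_morphology(
        chk$abp_pulses, fs = fs, subject_id = record$subject_id,
        segment_id = paste0(record$record_id, "-", nm),
        band_sd = config$morphology$band_sd)
      list(raw_abp = seg$abp, raw_ppg = seg$ppg, start = seg$start,
           pulses = chk$abp_pulses, morphology = morph)
    })
  c(base, list(segments = segments))
}

#' Provenance block for reproducible runs
#'
#' A deterministic fingerprint of a run: the configuration hash, the seed,
#' and the package and R versions. Attached to processed datasets and
#' training histories so outputs can be reproduced bit-for-bit.
#'
#' @param config a [bp_config()].
#' @param seed the run's master seed.
#' @return A named list.
#' @export
provenance <- function(config, seed) {
  list(
    config_hash = rlang::hash(config),
    seed = as.integer(seed),
    package_version = as.character(utils::packageVersion("abpmorph")),
    r_version = paste(R.version$major, R.version$minor, sep = ".")
  )
}

#' Process a record collection into a filtered morphology dataset
#'
#' Screens eligibility, runs [process_record()] on every eligible record,
#' applies the dataset-level post-filters (180 mmHg, 1.2 s, skewness 0.2)
#' and the 10-segments-per-subject cap, and logs per-stage rejection
#' counts.
#'
#' @param records list of `bp_record` objects.
#' @param config a [bp_config()].
#' @param seed seed for the per-subject subsampling.
#' @return A `bp_processed`: list with `manifest` (tibble: `subject_id`,
#'   `segment_id`, `age`, `gender`), `segments` (named list keyed by
#'   `segment_id`, each with `raw_ppg`, `morphology`, `demographics`), and
#'   `log` (stage rejection counts).
#' @export
process_records <- function(records, config = bp_config(), seed = 1L) {
  eligible <- scan_eligible(records, config$selection$min_duration,
                            config$selection$age_range)
  n_in <- length(records)
  containers <- purrr::map(eligible$record, process_record, config = config)
  accepted <- purrr::keep(containers, "accepted")
  morphs <- purrr::flatten(purrr::map(accepted, function(ct) {
    purrr::map(ct$segments, function(s) {
      list(morphology = s$morphology, raw_ppg = s$raw_ppg,
           demographics = ct$demographics)
    })
  }))
  pf <- postfilter(purrr::map(morphs, "morphology"),
                   max_abp = config$morphology$max_abp,
                   max_duration = config$morphology$max_duration,
                   min_skewness = config$morphology$min_skewness)
  kept <- morphs[pf$report$kept]
  manifest <- purrr::map_dfr(kept, function(m) {
    tibble::tibble(subject_id = m$morphology$subject_id,
                   segment_id = m$morphology$segment_id,
                   age = m$demographics$age, gender = m$demographics$gender)
  })
  capped <- cap_subject_segments(manifest, cap = config$morphology$cap,
                                 seed = seed)
  kept <- kept[match(capped$segment_id,
                     purrr::map_chr(kept, ~ .x$morphology$segment_id))]
  names(kept) <- capped$segment_id
  structure(
    list(manifest = capped, segments = kept,
         log = tibble::tibble(
           stage = c("input", "eligible", "quality_accepted",
                     "postfiltered", "capped"),
           n = c(n_in, nrow(eligible), 2L * length(accepted),
                 sum(pf$report$kept), nrow(capped))),
         provenance = provenance(config, seed)),
    class = "bp_processed"
  )
}

#' @export
print.bp_processed <- function(x, ...) {
  cat("<bp_processed>", nrow(x$manifest), "segments from",
      dplyr::n_distinct(x$manifest$subject_id), "subjects\n")
  print(x$log)
  invisible(x)
}

#' Generate a processed synthetic segment dataset directly
#'
#' Convenience generator for model experiments: draws subjects, renders
#' one 15-s paired segment at a time, runs the quality chain and the
#' morphology computation, and keeps segments until `n_segments` have been
#' accepted. Per-subject counts respect the 10-segment cap.
#'
#' @param n_segments number of accepted segments wanted.
#' @param seed integer master seed.
#' @param noise_sd additive PPG noise (normalized units).
#' @param config a [bp_config()].
#' @return A `bp_processed` (see [process_records()]).
#' @export
make_synthetic_dataset <- function(n_segments, seed = 1L, noise_sd = 0.01,
                                   config = bp_config()) {
  fs <- config$fs
  per_subject <- config$morphology$cap
  kept <- list()
  manifest <- list()
  subj_i <- 0L
  tries <- 0L
  while (length(kept) < n_segments && tries < 20L * n_segments) {
    subj_i <- subj_i + 1L
    subject <- make_subject(as.integer(seed) * 100000L + subj_i)
    for (k in seq_len(per_subject)) {
      if (length(kept) >= n_segments) break
      tries <- tries + 1L
      sr <- synth_record(subject, duration = 16, noise_sd = noise_sd,
                         seed = (as.integer(seed) * 131L + subj_i * 17L + k) %%
                           .Machine$integer.max, fs = fs)
      abp <- sr$record$abp[seq_len(15 * fs)]
      ppg <- sr$record$ppg[seq_len(15 * fs)]
      chk <- check_segment(abp, ppg, fs, config$quality)
      if (!chk$verdict$accepted) next
      seg_id <- sprintf("%s-seg%02d", subject$subject_id, k)
      morph <- compute_morphology(chk$abp_pulses, fs = fs,
                                  subject_id = subject$subject_id,
                                  segment_id = seg_id,
                                  band_sd = config$morphology$band_sd)
      if (max(morph$values) > config$morphology$max_abp ||
          morph$duration > config$morphology$max_duration ||
          morph$skewness <= config$morphology$min_skewness) next
      kept[[seg_id]] <- list(morphology = morph, raw_ppg = ppg,
                             demographics = list(age = subject$age,
                                                 gender = subject$gender),
                             truth = sr$truth)
      manifest[[seg_id]] <- tibble::tibble(
        subject_id = subject$subject_id, segment_id = seg_id,
        age = subject$age, gender = subject$gender)
    }
  }
  if (length(kept) < n_segments) {
    stop("could only generate ", length(kept), " accepted segments")
  }
  structure(list(manifest = dplyr::bind_rows(manifest), segments = kept,
                 log = tibble::tibble(stage = c("generated", "accepted"),
                                      n = c(tries, length(kept))),
                 provenance = provenance(config, seed)),
            class = "bp_processed")
}

#' Build the model-ready dataset from processed segments
#'
#' Prepares the two-channel 13-s input series for every segment, fits (or
#' reuses) the global target scaler and fixed length, and homogenizes
#' every scaled morphology.
#'
#' @param processed a `bp_processed`.
#' @param use_di include the demographic vector per sample.
#' @param scaler optionally a `bp_scaler` fitted on a training set; fitted
#'   here when `NULL`.
#' @param T_len optionally a fixed length from a training set.
#' @param config a [bp_config()].
#' @return A `bp_dataset`: list with `samples` (each: `prepared`, `target`,
#'   `x_di`, `segment_id`, `subject_id`), `manifest`, `scaler`,
#'   `fixed_length`.
#' @export
build_model_dataset <- function(processed, use_di = TRUE, scaler = NULL,
                                T_len = NULL, config = bp_config()) {
  morphs <- purrr::map(processed$segments, "morphology")
  if (is.null(scaler)) scaler <- scale_target_global(morphs)
  if (is.null(T_len)) T_len <- fixed_length(morphs, config$features$pad_steps)
  samples <- purrr::imap(processed$segments, function(s, id) {
    scaled <- s$morphology
    scaled$values <- scaler$transform(scaled$values)
    list(
      prepared = prepare_ppg_input(s$raw_ppg, config$fs,
                                   config$features$input_band,
                                   config$features$sg_window,
                                   config$features$sg_degree),
      target = homogenize_target(scaled, T_len, config$features$pad_steps),
      x_di = if (use_di) encode_demographics(s$demographics$age,
                                             s$demographics$gender) else NULL,
      segment_id = id, subject_id = s$morphology$subject_id
    )
  })
  structure(list(samples = unname(samples), manifest = processed$manifest,
                 scaler = scaler, fixed_length = T_len),
            class = "bp_dataset")
}

#' @export
print.bp_dataset <- function(x, ...) {
  cat("<bp_dataset>", length(x$samples), "samples, fixed length",
      x$fixed_length, "steps, pressure range",
      sprintf("[%.1f, %.1f] mmHg\n", x$scaler$min, x$scaler$max))
  invisible(x)
}

#' Subset a model dataset by segment ids
#' @param dataset a `bp_dataset`.
#' @param segment_ids character vector of segment ids to keep.
#' @return The subset `bp_dataset` (same scaler and fixed length).
#' @export
subset_dataset <- function(dataset, segment_ids) {
  keep <- purrr::map_lgl(dataset$samples, ~ .x$segment_id %in% segment_ids)
  out <- dataset
  out$samples <- dataset$samples[keep]
  out$manifest <- dplyr::filter(dataset$manifest,
                                .data$segment_id %in% segment_ids)
  out
}

#' Fit the model for one scenario fold
#'
#' Convenience wrapper: initializes weights, attaches the dataset's scaler
#' and fixed length, and trains.
#'
#' @param train_set a `bp_dataset`.
#' @param scenario scenario name (controls demographic input).
#' @param epochs,seed,... forwarded to [train_seq2seq()].
#' @param config a [bp_config()].
#' @return A trained `bp_seq2seq`.
#' @export
fit_fold <- function(train_set, scenario = "Mixno+DI", epochs = 10L,
                     seed = 1L, config = bp_config(), ...) {
  arch <- bp_architecture(config$model$enc_units, config$model$dec_units,
                          use_di = scenario_uses_di(scenario))
  model <- init_weights(arch, seed = seed)
  model$scaler <- train_set$scaler
  model$fixed_length <- train_set$fixed_length
  train_seq2seq(model, train_set, epochs = epochs,
                batch_size = config$training$batch_size,
                lr0 = config$training$lr, lambda = config$training$lambda,
                patience_decay = config$training$patience_decay,
                patience_stop = config$training$patience_stop,
                seed = seed, ...)
}
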