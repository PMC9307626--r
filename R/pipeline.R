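#' Run the analysis pipeline end to end from a single configuration
#'
#' Wires the stages together: 19F spectra are simulated (or read from
#' files in the package dialect), deconvolved by the BIC-selected
#' lineshape fit with optional Hamiltonian Monte Carlo, converted to
#' state populations and folding free energies (with differences against
#' the wild-type entry when present); an intensity profile is simulated
#' or read and its folding onset estimated; a coordinate ensemble is
#' simulated or read and its tunnel volume, contact frequencies and S2
#' order parameters computed. Every output table is written as CSV with
#' the seed and configuration hash in header comments, and a JSON run
#' manifest records versions, seed and the hash.
#'
#' The configuration is a list or a YAML/JSON file with top-level keys
#' `seed`, `outDir`, optional `temperature`, and any of the stage blocks
#' `spectra` (list of entries with either `foldedFraction`/`snr` to
#' simulate or `file` to read, plus `variant`/`linkerL`), `profile`
#' (either `onsetL`/`lengths`/`concNoiseFrac` or `fileU`/`fileF`) and
#' `ensemble` (`nFrames`/`ncLength`/`mobility` or `file`). Validation
#' reports all problems at once; referenced paths must exist.
#'
#' @param config list, or path to a YAML/JSON configuration file.
#' @param hmc run posterior sampling for each spectrum? (MAP-only when
#'   `FALSE`; much faster.)
#' @return (invisibly) a list with elements `populations`, `energetics`,
#'   `profile`, `onset`, `ensemble` tables and `manifest`.
#' @examples
#' \donttest{
#' cfg <- list(seed = 1, outDir = tempfile(),
#'             spectra = list(list(variant = "WT", linkerL = 34,
#'                                 foldedFraction = 0.59, snr = 20)))
#' res <- runPipeline(cfg, hmc = FALSE)
#' }
#' @export
runPipeline <- function(config, hmc = TRUE) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      stop("config error: file not found: ", config, call. = FALSE)
    config <- if (grepl("\\.json$", config))
      jsonlite::read_json(config, simplifyVector = TRUE) else
        yaml::read_yaml(config)
  }
  problems <- character()
  if (is.null(config$seed)) problems <- c(problems, "missing 'seed'")
  if (is.null(config$outDir)) problems <- c(problems, "missing 'outDir'")
  for (s in config$spectra)
    if (!is.null(s$file) && !file.exists(s$file))
      problems <- c(problems, paste0("spectrum file not found: ", s$file))
  for (key in c("fileU", "fileF"))
    if (!is.null(config$profile[[key]]) &&
        !file.exists(config$profile[[key]]))
      problems <- c(problems,
                    paste0("profile file not found: ", config$profile[[key]]))
  if (!is.null(config$ensemble$file) && !file.exists(config$ensemble$file))
    problems <- c(problems,
                  paste0("ensemble file not found: ", config$ensemble$file))
  if (length(problems))
    stop("config error:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)

  seed <- as.integer(config$seed)
  cfgHash <- rlang::hash(config[setdiff(names(config), "outDir")])
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  cfg <- thermoConfig(temperature = config$temperature %||% 298.15)
  stamp <- c(sprintf("# seed: %d", seed),
             sprintf("# config_hash: %s", cfgHash))
  writeTable <- function(df, name) {
    path <- file.path(config$outDir, name)
    writeLines(stamp, path)
    suppressWarnings(write.table(df, path, sep = ",", row.names = FALSE,
                                 append = TRUE, qmethod = "double"))
    path
  }
  outputs <- character()
  results <- list()

  if (length(config$spectra)) {
    pops <- list()
    for (i in seq_along(config$spectra)) {
      s <- config$spectra[[i]]
      spec <- if (!is.null(s$file)) readSpectrum(s$file) else {
        truth0 <- groundTruthSpectrum(s$foldedFraction)
        truth <- groundTruthSpectrum(s$foldedFraction,
          noiseSd = noiseForSnr(truth0, snr = s$snr %||% 20))
        fourierTransform(simulateFid(truth, seed = deriveSeed(seed, i)),
                         zeroFillFactor = 1L)
      }
      mid <- mean(range(spec@axis))
      halfw <- diff(range(spec@axis)) / 4
      spec <- withNoiseEstimate(spec,
        exclusionWindows = list(c(mid - halfw, mid + halfw)))
      fit <- selectModel(spec)
      if (hmc && nrow(peakTable(fit)) >= 2)
        fit <- samplePosterior(spec, fit,
                               nChains = config$fit$chains %||% 4L,
                               nWarmup = config$fit$warmup %||% 1000L,
                               nDraws = config$fit$draws %||% 1000L,
                               seed = deriveSeed(seed, 100L + i))
      pop <- tryCatch(populationsFromFit(fit), error = function(e) {
        u <- peakTable(fit)
        detectionBound(fit@noiseSd, list(fwhm = u$fwhm[1], area = u$area[1]))
      })
      pops[[i]] <- data.frame(variant = s$variant %||% sprintf("v%d", i),
                              linker_L = s$linkerL %||% NA_integer_,
                              p_f = pop@pF, sd_pf = pop@sdPf,
                              bounded = pop@bounded)
      results$fits[[i]] <- fit
      results$popObjects[[i]] <- pop
    }
    popTab <- do.call(rbind, pops)
    en <- do.call(rbind, lapply(seq_len(nrow(popTab)), function(i) {
      deltaGFolding(results$popObjects[[i]], cfg,
                    variant = popTab$variant[i],
                    linkerL = popTab$linker_L[i])
    }))
    results$populations <- popTab
    results$energetics <- en
    outputs <- c(outputs, writeTable(popTab, "populations.csv"),
                 writeTable(en, "energetics.csv"))
    wt <- which(popTab$variant == "WT")
    if (length(wt) == 1L && nrow(en) > 1L) {
      dd <- do.call(rbind, lapply(setdiff(seq_len(nrow(en)), wt),
                                  function(i) ddgFolding(en[i, ], en[wt, ])))
      results$ddg <- dd
      outputs <- c(outputs, writeTable(dd, "ddg.csv"))
    }
  }

  if (length(config$profile)) {
    p <- config$profile
    if (!is.null(p$fileF)) {
      tabF <- read.csv(p$fileF, comment.char = "#")
      attr(tabF, "channel") <- "F"
    } else {
      sim <- simulateIntensityProfile(
        onsetL = p$onsetL %||% 34, steepness = p$steepness %||% 0.5,
        lengths = p$lengths %||% c(21, 31, 34, 37, 42, 67),
        concNoiseFrac = p$concNoiseFrac %||% 0,
        seed = deriveSeed(seed, 999L))
      tabF <- sim$F
    }
    prof <- relativeProfile(tabF, unique(tabF$residue),
                            referenceL = max(tabF$linker_L))
    onset <- foldingOnset(prof)
    results$profile <- prof
    results$onset <- onset
    outputs <- c(outputs, writeTable(prof, "profile.csv"))
  }

  if (length(config$ensemble)) {
    e <- config$ensemble
    ens <- if (!is.null(e$file)) readEnsemblePdb(e$file, roles = e$roles)
      else simulateEnsemble(ensembleSpec(
        nFrames = e$nFrames %||% 25L, ncLength = e$ncLength %||% 10L,
        mobility = e$mobility %||% 0.3, seed = deriveSeed(seed, 777L)))
    ca <- ens@atoms$role == "NC" & ens@atoms$name == "CA"
    spec <- volumeGridSpec(frameCoords(ens, 1L)[ca, , drop = FALSE],
                           sphereRadius = e$sphereRadius %||% 20,
                           gridSpacing = e$gridSpacing %||% 2.0)
    vol <- tunnelVolume(atomFrame(ens, 1L)[
      atomFrame(ens, 1L)$role != "NC", ], spec)
    contacts <- contactFrequencies(ens)
    s2 <- orderParameters(ens)
    results$ensemble <- list(volume = vol, contacts = contacts, s2 = s2)
    outputs <- c(outputs, writeTable(contacts, "contacts.csv"),
                 writeTable(s2, "s2.csv"),
                 writeTable(data.frame(volume_A3 = vol), "volume.csv"))
  }

  manifest <- list(package = "rncfold",
                   version = as.character(utils::packageVersion("rncfold")),
                   rVersion = R.version.string, seed = seed,
                   configHash = cfgHash, outputs = basename(outputs),
                   timestampUtc = format(Sys.time(), tz = "UTC",
                                         "%Y-%m-%dT%H:%M:%SZ"))
  jsonlite::write_json(manifest, file.path(config$outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
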