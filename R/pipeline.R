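#' Pipeline configuration
#'
#' Bundles the stage toggles and analysis policies for [run_pipeline()].
#' Defaults mirror the standard recording parameters (K = 3 tapers,
#' TW = 2, N = 512 samples at 1017.375 Hz, R = 500 µm, sigma = 0.4 S/m,
#' q = 0.05, 95th-percentile shuffle null).
#'
#' @param generator A [generator_config()], or NULL when `input` is given.
#' @param input Path to a session container ([write_session()]) or a list
#'   of paths (one per session); overrides `generator`.
#' @param n_sessions Number of sessions to generate (seeded independently)
#'   when `generator` is used; across-session statistics need >= 5.
#' @param stages Character subset of
#'   c("preprocess", "laminar", "spectral", "granger", "attention").
#' @param taper A [taper_spec()].
#' @param bands A [band_set()].
#' @param gc List: `order` (NULL = BIC), `p_max`, `conditioning_cap`,
#'   `n_shuffles` (0 disables thresholds), `percentile`, `scope`.
#' @param stats List: `q` (FDR level).
#' @param seed Master seed.
#' @param outdir Output directory.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(generator = NULL, input = NULL, n_sessions = 6,
                            stages = c("preprocess", "laminar", "spectral",
                                       "granger", "attention"),
                            taper = taper_spec(),
                            bands = band_set(),
                            gc = list(order = NULL, p_max = 12,
                                      conditioning_cap = 8, n_shuffles = 0,
                                      percentile = 95, scope = "within"),
                            stats = list(q = 0.05),
                            seed = 1, outdir = tempfile("laminarGC_run_")) {
  if (is.null(generator) && is.null(input))
    stop("either a generator config or an input path is required")
  stages <- match.arg(stages, several.ok = TRUE)
  if ("attention" %in% stages && !"spectral" %in% stages)
    stop("the attention stage needs the spectral stage")
  structure(list(generator = generator, input = input,
                 n_sessions = as.integer(n_sessions), stages = stages,
                 taper = taper, bands = bands, gc = gc, stats = stats,
                 seed = as.integer(seed), outdir = outdir),
            class = "pipeline_config")
}

write_table <- function(df, dir, name, manifest) {
  path <- file.path(dir, name)
  utils::write.csv(df, path, row.names = FALSE)
  c(manifest, path)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order on one or more sessions:
#' generate/load, bipolar re-referencing, iCSD laminar alignment (from a
#' stimulus-onset-aligned companion epoch), per-condition multitaper band
#' power with attend-OUT pooling, within-probe conditional GC for all
#' directed derivation pairs, and across-session attention statistics
#' (band-power MI with Wilcoxon/FDR, cGC dominance matrices, compartment
#' pooling, influencer edge list). Results are written as CSV tables plus
#' a JSON run report; identical config and seed give identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return A `run_report` (invisibly also written to the output
#'   directory): per-stage runtimes, warnings, and an output manifest with
#'   checksums.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- character(0)
  warnings_log <- character(0)
  note <- function(w) warnings_log <<- c(warnings_log, w)
  timings <- list()
  tic <- function() Sys.time()
  toc <- function(t0) as.numeric(difftime(Sys.time(), t0, units = "secs"))

  # ---- sessions ----
  t0 <- tic()
  if (!is.null(config$input)) {
    paths <- if (is.character(config$input)) as.list(config$input) else config$input
    sessions <- lapply(paths, read_session)
    align_sessions <- NULL
  } else {
    seeds <- derive_seeds(config$seed, config$n_sessions)
    sessions <- lapply(seq_len(config$n_sessions), function(i) {
      cfg <- config$generator
      cfg$seed <- seeds[i]
      generate_session(cfg)
    })
    align_sessions <- if ("laminar" %in% config$stages) {
      lapply(seq_len(config$n_sessions), function(i) {
        cfg <- config$generator
        cfg$seed <- seeds[i]
        cfg$epoch_alignment <- "stimulus_onset"
        generate_session(cfg)
      })
    }
  }
  n_ses <- length(sessions)
  timings$load <- toc(t0)

  # ---- preprocess ----
  if ("preprocess" %in% config$stages) {
    t0 <- tic()
    sessions <- lapply(sessions, bipolar_rereference)
    timings$preprocess <- toc(t0)
  }

  # ---- laminar ----
  alignments <- NULL
  if ("laminar" %in% config$stages && !is.null(align_sessions)) {
    t0 <- tic()
    alignments <- lapply(align_sessions, function(s) {
      probes <- unique(s$probe_of_channel)
      al <- lapply(probes, function(p) {
        idx <- which(s$probe_of_channel == p)
        avg <- apply(s$lfp[, idx, , drop = FALSE], c(2, 3), mean)
        csd <- compute_icsd(avg, spacing = s$spacing,
                            times = (seq_len(dim(s$lfp)[3]) - 1) / s$fs * 1000)
        align_probe(csd, area = p, spacing = s$spacing,
                    mua = if (!is.null(s$mua)) s$mua[, idx, , drop = FALSE],
                    onset_sample = if (!is.null(s$mua)) attr(s$mua, "onset_sample"))
      })
      names(al) <- probes
      al
    })
    ref_tab <- do.call(rbind, lapply(seq_len(n_ses), function(i)
      data.frame(session = i, probe = names(alignments[[i]]),
                 reference_channel = vapply(alignments[[i]], `[[`, numeric(1),
                                            "reference_channel"))))
    manifest <- write_table(ref_tab, config$outdir, "laminar_alignment.csv", manifest)
    timings$laminar <- toc(t0)
  }

  # ---- spectral ----
  band_power <- NULL
  if ("spectral" %in% config$stages) {
    t0 <- tic()
    bn <- names(config$bands)
    band_power <- lapply(seq_len(n_ses), function(i) {
      s <- sessions[[i]]
      pooled_out <- pool_attend_out(which(s$condition == "OUT1"),
                                    which(s$condition == "OUT2"),
                                    seed = config$seed + i)
      sets <- list(RF = which(s$condition == "RF"), OUT = sort(pooled_out))
      lapply(sets, function(trs) {
        pw <- multitaper_power(s$lfp[trs, , , drop = FALSE], s$fs, config$taper)
        band_average(pw, config$bands)
      })
    })
    tab <- do.call(rbind, lapply(seq_len(n_ses), function(i) {
      do.call(rbind, lapply(names(band_power[[i]]), function(cond) {
        bp <- band_power[[i]][[cond]]
        data.frame(session = i, condition = cond,
                   channel = rep(seq_len(nrow(bp)), times = ncol(bp)),
                   band = rep(colnames(bp), each = nrow(bp)),
                   power = as.vector(bp))
      }))
    }))
    manifest <- write_table(tab, config$outdir, "band_power.csv", manifest)
    timings$spectral <- toc(t0)
  }

  # ---- granger ----
  cgc_band <- NULL
  if ("granger" %in% config$stages) {
    t0 <- tic()
    if (!inherits(sessions[[1]], "bipolar_recording"))
      stop("the granger stage needs the preprocess stage (bipolar derivations)")
    cgc_band <- lapply(seq_len(n_ses), function(i) {
      res <- pairwise_cgc(sessions[[i]], scope = config$gc$scope,
                          conditioning_cap = config$gc$conditioning_cap,
                          order = config$gc$order, seed = config$seed + i)
      lapply(res, function(r) list(band = band_average(r, config$bands),
                                   pairs = r$pairs))
    })
    tab <- do.call(rbind, lapply(seq_len(n_ses), function(i) {
      do.call(rbind, lapply(names(cgc_band[[i]]), function(cond) {
        b <- cgc_band[[i]][[cond]]
        data.frame(session = i, condition = cond,
                   from = rep(b$pairs[, "from"], times = ncol(b$band)),
                   to = rep(b$pairs[, "to"], times = ncol(b$band)),
                   band = rep(colnames(b$band), each = nrow(b$band)),
                   cgc = as.vector(b$band))
      }))
    }))
    manifest <- write_table(tab, config$outdir, "cgc_band.csv", manifest)
    timings$granger <- toc(t0)
  }

  # ---- attention statistics ----
  influencers <- NULL
  if ("attention" %in% config$stages) {
    t0 <- tic()
    bn <- names(config$bands)
    q <- config$stats$q
    # band-power MI per session, tested across sessions within band families
    mi_arr <- simplify2array(lapply(band_power, function(bp)
      modulation_index(bp$RF, bp$OUT))) # channel x band x session
    nch <- dim(mi_arr)[1]
    diffs <- matrix(aperm(mi_arr, c(3, 1, 2)), nrow = nch * length(bn),
                    byrow = TRUE)
    fam <- factor(rep(bn, each = nch), levels = bn)
    if (n_ses >= 5) {
      mi_tests <- wilcoxon_fdr(diffs, family = fam, q = q)
      mi_tests$channel <- rep(seq_len(nch), times = length(bn))
      mi_tests$mi_mean <- rowMeans(diffs)
      manifest <- write_table(mi_tests, config$outdir, "power_mi_tests.csv", manifest)
    } else {
      note("fewer than 5 sessions: across-session MI tests skipped")
    }
    # cGC dominance + compartment pooling (within-probe scope only)
    if (!is.null(cgc_band) && n_ses >= 5) {
      pairs <- cgc_band[[1]]$RF$pairs
      chans <- sort(unique(as.vector(pairs)))
      nloc <- length(chans)
      edge_rows <- list()
      for (b in bn) {
        arr <- array(0, c(n_ses, nloc, nloc))
        for (i in seq_len(n_ses)) {
          bb <- cgc_band[[i]]$RF$band[, b]
          for (k in seq_len(nrow(pairs)))
            arr[i, match(pairs[k, "from"], chans), match(pairs[k, "to"], chans)] <- bb[k]
        }
        dm <- dominance_matrix(arr, q = q)
        if (!is.null(alignments)) {
          al <- alignments[[1]][[1]]
          comp <- al$compartment
          mid <- sessions[[1]]$derivation_midpoint[chans]
          dcomp <- assign_compartments(
            (al$reference_channel - mid) * sessions[[1]]$spacing / 1000, al$area)
          pooled <- compartment_pool(dm$matrix, dcomp)
          edge_rows[[b]] <- summarize_influencers(stats::setNames(list(pooled), b))
        }
      }
      if (length(edge_rows)) {
        influencers <- do.call(rbind, edge_rows)
        manifest <- write_table(influencers, config$outdir, "influencers.csv", manifest)
      }
    }
    timings$attention <- toc(t0)
  }

  report <- structure(list(
    stages = config$stages, n_sessions = n_ses, seed = config$seed,
    timings = timings, warnings = warnings_log,
    manifest = data.frame(file = basename(manifest),
                          md5 = unname(tools::md5sum(manifest))),
    package_version = as.character(utils::packageVersion("laminarGC"))
  ), class = "run_report")
  jsonlite::write_json(unclass(report), file.path(config$outdir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d session(s), stages: %s\n", x$n_sessions,
              paste(x$stages, collapse = ", ")))
  cat(sprintf("  outputs: %s\n", paste(x$manifest$file, collapse = ", ")))
  if (length(x$warnings)) cat("  warnings:", length(x$warnings), "\n")
  invisible(x)
}

#' Flatten compartment matrices into an influencer edge list
#'
#' Turns per-band compartment-pooled dominance (or MI) matrices into a
#' flat table of significant directed edges suitable for plotting an
#' influencer diagram.
#'
#' @param mats Named list (band -> 3 x 3 compartment matrix with dimnames;
#'   zero or NA entries are not edges).
#' @return data.frame with `source`, `target`, `band`, `strength`.
#' @export
summarize_influencers <- function(mats) {
  rows <- lapply(names(mats), function(b) {
    m <- mats[[b]]
    idx <- which(is.finite(m) & m != 0, arr.ind = TRUE)
    if (!nrow(idx)) return(NULL)
    data.frame(source = rownames(m)[idx[, 1]], target = colnames(m)[idx[, 2]],
               band = b, strength = m[idx])
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(source = character(0), target = character(0),
                      band = character(0), strength = numeric(0))
  out
}
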