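#' Write a trap trace to CSV with a JSON metadata sidecar
#'
#' The trace is written as a three-column CSV (`t_s`, `x_nm`, `f_pN`); the
#' configuration metadata goes to `<path>.json` so a record can be
#' regenerated exactly.
#'
#' @param trace A `trap_trace` data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(all(c("t_s", "x_nm", "f_pN") %in% names(trace)))
  write.csv(as.data.frame(trace)[, c("t_s", "x_nm", "f_pN")], path,
            row.names = FALSE)
  meta <- attr(trace, "meta")
  if (!is.null(meta)) {
    strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
    jsonlite::write_json(strip(meta), paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' Read a trap trace written by [write_trace()]
#'
#' @param path CSV path; `<path>.json` is read as metadata when present.
#'   If the force column is absent but the sidecar carries `k_trap`, force
#'   is reconstructed as `k_trap * x`.
#' @return A `trap_trace` data frame.
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("trace file has no data rows: ", path)
  header <- strsplit(gsub('"', "", lines[1]), ",")[[1]]
  if (!all(c("t_s", "x_nm") %in% header))
    stop("line 1: header must contain t_s and x_nm")
  nf <- lengths(regmatches(lines, gregexpr(",", lines))) + 1
  bad <- which(nf != nf[1])
  if (length(bad) > 0)
    stop(sprintf("malformed CSV at line %d: expected %d fields, found %d",
                 bad[1], nf[1], nf[bad[1]]))
  df <- read.csv(path)
  meta <- NULL
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$cfg$sample_hz) && meta$cfg$sample_hz <= 0)
      stop("sidecar validation: sample_hz must be > 0")
  } else {
    meta <- list(cfg = list(), unknown_meta = TRUE)
  }
  if (!("f_pN" %in% names(df))) {
    k_trap <- meta$cfg$k_trap
    if (is.null(k_trap))
      stop("no f_pN column and no k_trap in sidecar: cannot reconstruct ",
           "force")
    df$f_pN <- k_trap * df$x_nm
  }
  attr(df, "meta") <- meta
  class(df) <- c("trap_trace", "data.frame")
  df
}

#' Run an end-to-end reproduction pipeline
#'
#' Ties simulation, event detection and fitting together for the headline
#' analyses: `"single_molecule"` (relative binding frequency vs calcium plus
#' a K fit), `"mini_ensemble"` (threshold-detected event frequency vs
#' calcium from simulated 10-s traces), `"motility"` (speed vs ATP curves at
#' low and high calcium with the critical-ATP breakpoint), and `"fiber"`
#' (half-sarcomere force-pCa curve with its Hill fit). Sizes default to
#' reduced, desk-scale settings; each stage derives its own seed from
#' `seed` so stages stay reproducible independently.
#'
#' @param target One of `"single_molecule"`, `"mini_ensemble"`,
#'   `"motility"`, `"fiber"`.
#' @param seed Integer seed for the whole pipeline.
#' @param reg,mp Model parameter objects.
#' @param out_dir Optional directory; results are written there as JSON/CSV.
#' @param scale Multiplier on the default replicate counts (default 1).
#' @return A list of results; contents depend on `target`.
#' @export
run_reproduction <- function(target = c("single_molecule", "mini_ensemble",
                                        "motility", "fiber"),
                             seed = 1, reg = regulation_params(),
                             mp = motor_params(), out_dir = NULL,
                             scale = 1) {
  target <- match.arg(target)
  res <- switch(target,
    single_molecule = {
      pcas <- c(4, 5, 6, 7, 9)
      rows <- lapply(seq_along(pcas), function(i) {
        f <- single_molecule_frequency(pcas[i], reg, mp,
                                       n_events_target = ceiling(30 * scale),
                                       max_time_s = 240 * scale,
                                       seed = seed + i)
        data.frame(pca = pcas[i], rel_freq = f$relative,
                   freq_hz = f$frequency_hz, n_events = f$n_events,
                   upper_bound = f$upper_bound)
      })
      curve <- do.call(rbind, rows)
      fit_curve <- curve[!curve$upper_bound, c("pca", "rel_freq")]
      list(curve = curve, k_fit = fit_K(fit_curve, reg))
    },
    mini_ensemble = {
      set.seed(seed)
      pcas <- c(5, 6, 7, 9)
      n_traces <- ceiling(10 * scale)
      cfg <- trap_config(k_trap = 0.038, n_motors = 14, atp_uM = 100)
      dp <- detection_params()
      rows <- lapply(pcas, function(p) {
        cfg$pca <- p
        n_ev <- 0
        for (k in seq_len(n_traces))
          n_ev <- n_ev + nrow(detect_threshold(simulate_trace(cfg, reg, mp),
                                               dp))
        data.frame(pca = p, freq_hz = n_ev / (n_traces * cfg$duration_s),
                   n_events = n_ev)
      })
      list(frequency = do.call(rbind, rows), n_traces = n_traces)
    },
    motility = {
      atp <- c(5, 10, 20, 30, 45, 60, 80, 100, 150, 250, 500, 1000, 2000,
               4000)
      curve <- motility_curve(c(5, 9), atp,
                              replicates = max(3, ceiling(5 * scale)),
                              seed = seed)
      list(curve = curve,
           critical_atp_uM = tryCatch(critical_atp(curve, 9),
                                      warning = function(w) NA_real_))
    },
    fiber = {
      cfg <- fiber_config(replicates = max(2, ceiling(3 * scale)),
                          seed = seed)
      curve <- simulate_fiber_force(cfg, reg, mp)
      list(curve = curve,
           hill = fit_hill(curve$pca, curve$force_norm,
                           ifelse(curve$sd_pN > 0,
                                  curve$sd_pN / curve$force_pN[
                                    which.min(curve$pca)], NA)))
    })
  res$manifest <- list(target = target, seed = seed,
                       reg = unclass(reg), mp = unclass(mp),
                       package_version = as.character(
                         utils::packageVersion("rtfsim")))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(res)) {
      obj <- res[[nm]]
      fn <- file.path(out_dir, paste0(target, "_", nm))
      if (is.data.frame(obj)) write.csv(obj, paste0(fn, ".csv"),
                                        row.names = FALSE)
      else jsonlite::write_json(no_model(obj), paste0(fn, ".json"),
                                auto_unbox = TRUE, digits = NA,
                                force = TRUE, null = "null")
    }
  }
  res
}

#' Read a run configuration from JSON
#'
#' A run configuration is a JSON object with any of the blocks
#' `regulation`, `motor`, `trap`, `motility`, `fiber`, `detection`, plus an
#' optional global `seed`. Each block is validated by its constructor
#' ([regulation_params()], [motor_params()], [trap_config()],
#' [motility_config()], [fiber_config()], [detection_params()]); unknown
#' blocks or unknown keys within a block are rejected.
#'
#' @param path Path to the JSON file.
#' @return Named list of validated parameter objects (only the blocks
#'   present in the file), plus `seed` if given.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  constructors <- list(regulation = regulation_params, motor = motor_params,
                       trap = trap_config, motility = motility_config,
                       fiber = fiber_config, detection = detection_params)
  unknown <- setdiff(names(raw), c(names(constructors), "seed"))
  if (length(unknown) > 0)
    stop("unknown config block(s): ", paste(unknown, collapse = ", "))
  out <- list()
  for (block in intersect(names(raw), names(constructors))) {
    fn <- constructors[[block]]
    bad <- setdiff(names(raw[[block]]), names(formals(fn)))
    if (length(bad) > 0)
      stop(sprintf("unknown key(s) in [%s]: %s", block,
                   paste(bad, collapse = ", ")))
    out[[block]] <- do.call(fn, raw[[block]])
  }
  if (!is.null(raw$seed)) out$seed <- as.integer(raw$seed)
  out
}

# drop unserialisable fitted-model objects before JSON export
no_model <- function(x) {
  if (is.list(x)) {
    x$model <- NULL
    lapply(x, function(el) if (is.list(el)) no_model(el) else el)
  } else x
}
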