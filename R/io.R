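#' Load a study manifest
#'
#' Parses the manifest JSON, validates the schema fields, checks that
#' every referenced trace file exists, and returns the sweep table plus
#' a lazy loader.  When a trace is loaded, its CSV metadata header is
#' cross-checked against the manifest record; any disagreement is an
#' error naming the sweep.
#'
#' @param path manifest JSON path (from [generate_study()] or real
#'   exports in the same layout).
#' @return A list of class \code{"study_manifest"}: \code{sweeps}
#'   (data.frame), \code{root}, \code{seed}, \code{ground_truth_path},
#'   and \code{load_trace(i)} returning the i-th sweep as a
#'   [tevc_trace()].
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  req <- c("format", "sweeps")
  miss <- setdiff(req, names(m))
  if (length(miss))
    stop("manifest is missing field(s): ", paste(miss, collapse = ", "))
  sw <- as.data.frame(m$sweeps)
  cols <- c("path", "construct", "cell_id", "day", "solution", "holding_mV")
  miss <- setdiff(cols, names(sw))
  if (length(miss))
    stop("manifest sweep records are missing: ", paste(miss, collapse = ", "))
  root <- dirname(normalizePath(path))
  gone <- !file.exists(file.path(root, sw$path))
  if (any(gone))
    stop("manifest references missing trace file(s): ",
         paste(utils::head(sw$path[gone], 5), collapse = ", "))
  gt <- if (!is.null(m$ground_truth)) file.path(root, m$ground_truth) else NULL

  load_trace <- function(i) {
    rec <- sw[i, ]
    tr <- read_trace_csv(file.path(root, rec$path))
    for (f in c("construct", "cell_id", "day", "solution")) {
      if (!identical(tr[[f]], rec[[f]]))
        stop("sweep ", rec$path, ": header ", f, " '", tr[[f]],
             "' disagrees with manifest '", rec[[f]], "'")
    }
    if (abs(tr$holding_mV - rec$holding_mV) > 1e-9)
      stop("sweep ", rec$path, ": header holding_mV ", tr$holding_mV,
           " disagrees with manifest ", rec$holding_mV)
    tr
  }
  structure(list(sweeps = sw, root = root,
                 seed = if (!is.null(m$seed)) m$seed else NA,
                 ground_truth_path = gt, load_trace = load_trace),
            class = "study_manifest")
}

#' Group statistics with an optional reference comparison
#'
#' Mean, SEM (= sd/sqrt(n)) and n of a numeric sample; when a reference
#' sample is supplied, a two-sided Welch two-sample t-test p-value
#' against it.  With n = 1 on either side the p-value is undefined and
#' flagged NA rather than fabricated.
#'
#' @param values numeric vector.
#' @param reference optional numeric reference sample (e.g. the WT
#'   group).
#' @return A list of class \code{"group_stat"}: \code{mean}, \code{sem},
#'   \code{n}, \code{comparison_p}.
#' @export
aggregate_stat <- function(values, reference = NULL) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 1L) stop("need at least one finite value")
  sem <- if (n > 1L) stats::sd(values) / sqrt(n) else NA_real_
  p <- NA_real_
  if (!is.null(reference)) {
    reference <- reference[is.finite(reference)]
    if (n > 1L && length(reference) > 1L) {
      p <- if (stats::sd(values) == 0 && stats::sd(reference) == 0 &&
               mean(values) == mean(reference)) 1
           else stats::t.test(values, reference)$p.value
    }
  }
  structure(list(mean = mean(values), sem = sem, n = n, comparison_p = p),
            class = "group_stat")
}

#' Run the full analysis chain on a study
#'
#' Executes, per construct: sweep summaries; apparent kinetics (tau_on,
#' tau_decay at \code{kinetics_mV} in Na+, tau_off from the same sweeps'
#' off segments); same-day WT normalization of peak photocurrents;
#' per-cell stationary I-V curves and reversal potentials per solution;
#' per-cell reversal shifts dErev = E_rev,X - E_rev,Na; GHK permeability
#' ratios from the mean shifts; and the excluded-volume pore fit.
#' Welch's two-sided t-test compares each construct with WT (no
#' multiple-testing correction).  Deterministic given (dataset, config).
#'
#' @param manifest a [load_manifest()] result or a manifest path.
#' @param T_K temperature for the GHK conversions, K.
#' @param radii ion radius table for the pore regression.
#' @param kinetics_mV holding potential for the kinetic fits.
#' @param basis current basis for I-V assembly.
#' @param steady_window_ms stationary-current window, ms.
#' @param out_dir optional directory; when given, the report tables are
#'   written as CSV plus a JSON bundle.
#' @return A list of class \code{"study_report"}: data.frames
#'   \code{kinetics}, \code{normalized}, \code{erev}, \code{delta_erev},
#'   \code{permeability}, \code{pore}, and list \code{pore_fits}.
#' @export
run_pipeline <- function(manifest, T_K = 293.15, radii = ion_radii(),
                         kinetics_mV = -120, basis = "stationary",
                         steady_window_ms = 50, out_dir = NULL) {
  if (is.character(manifest)) manifest <- load_manifest(manifest)
  stopifnot(inherits(manifest, "study_manifest"))
  sw <- manifest$sweeps
  if (!"WT" %in% sw$construct)
    stop("manifest has no WT construct; WT is required as reference")
  consts <- phys_constants(T_K)

  summaries <- lapply(seq_len(nrow(sw)), function(i) {
    summarize_sweep(manifest$load_trace(i), steady_window_ms)
  })

  # --- kinetics at kinetics_mV in Na -------------------------------------
  kin_idx <- which(sw$solution == "Na" & sw$holding_mV == kinetics_mV)
  kinetics <- do.call(rbind, lapply(kin_idx, function(i) {
    sweep_kinetics(manifest$load_trace(i))
  }))

  # --- same-day WT normalization of peak currents ------------------------
  normalized <- NULL
  for (i in kin_idx) {
    s <- summaries[[i]]
    wt_idx <- which(sw$construct == "WT" & sw$solution == "Na" &
                    sw$holding_mV == kinetics_mV & sw$day == s$day)
    if (!length(wt_idx))
      stop("no same-day WT sweep for day '", s$day, "'; days with WT: ",
           paste(unique(sw$day[sw$construct == "WT"]), collapse = ", "))
    wt_peak <- mean(vapply(wt_idx, function(j) summaries[[j]]$I_p, 0))
    normalized <- rbind(normalized, data.frame(
      construct = s$construct, cell_id = s$cell_id, day = s$day,
      I_p_uA = s$I_p, Iss_over_Ip = s$Iss_over_Ip,
      normalized_photocurrent = normalize_to_reference(s$I_p, wt_peak)))
  }

  # --- per-cell reversal potentials --------------------------------------
  key <- interaction(sw$construct, sw$cell_id, sw$day, sw$solution, drop = TRUE)
  erev <- do.call(rbind, lapply(split(seq_len(nrow(sw)), key), function(idx) {
    ivc <- build_iv(summaries[idx], basis = basis)
    est <- estimate_erev(ivc)
    data.frame(construct = est$construct, cell_id = sw$cell_id[idx[1]],
               day = sw$day[idx[1]], solution = est$solution,
               E_rev_mV = est$E_rev_mV,
               extrapolated = est$flag_extrapolated)
  }))
  rownames(erev) <- NULL

  # --- per-cell dErev vs Na, aggregated per construct/ion ----------------
  delta <- NULL
  for (cn in unique(erev$construct)) {
    ec <- erev[erev$construct == cn, ]
    for (ion in setdiff(unique(ec$solution), "Na")) {
      dvals <- unlist(lapply(unique(ec$cell_id), function(cl) {
        ex <- ec$E_rev_mV[ec$cell_id == cl & ec$solution == ion]
        en <- ec$E_rev_mV[ec$cell_id == cl & ec$solution == "Na"]
        if (length(ex) == 1L && length(en) == 1L) ex - en else numeric(0)
      }))
      if (!length(dvals)) next
      st <- aggregate_stat(dvals)
      delta <- rbind(delta, data.frame(
        construct = cn, ion = ion, delta_erev_mV = st$mean,
        sem_mV = st$sem, n = st$n))
    }
  }

  # --- GHK ratios and pore fit per construct -----------------------------
  perm <- NULL; pore <- NULL; pore_fits <- list()
  for (cn in unique(delta$construct)) {
    dc <- delta[delta$construct == cn, ]
    ratios <- c(Na = 1)
    for (k in seq_len(nrow(dc))) {
      d <- structure(list(ion = dc$ion[k], value = dc$delta_erev_mV[k],
                          sem = dc$sem_mV[k], n = dc$n[k], construct = cn),
                     class = "delta_erev")
      pr <- ghk_ratio(d, consts)
      ratios[pr$ion] <- pr$ratio
      perm <- rbind(perm, data.frame(
        construct = cn, ion = pr$ion, ratio = pr$ratio,
        delta_erev_mV = pr$source_delta_mV, sem = pr$sem, n = pr$n,
        T_K = consts$T))
    }
    n_ions <- length(intersect(names(ratios), names(radii)))
    if (n_ions < 3L) {
      warning("construct ", cn, ": only ", n_ions,
              " ions with radii; pore fit skipped")
      next
    }
    if (length(ratios) < length(unique(sw$solution)))
      warning("construct ", cn, ": pore fit proceeds on ",
              length(ratios), " of ", length(unique(sw$solution)),
              " solutions")
    pf <- fit_excluded_volume(ratios, radii)
    pore_fits[[cn]] <- pf
    pore <- rbind(pore, data.frame(
      construct = cn, a = pf$a, b = pf$b, r2 = pf$r2,
      d_min_A = pf$d_min_A, R_Na_est_A = pf$R_Na_est_A,
      n_ions = length(pf$ions_used)))
  }

  # --- Welch comparisons vs WT -------------------------------------------
  comp <- NULL
  for (cn in setdiff(unique(kinetics$construct), "WT")) {
    for (v in c("tau_on_ms", "tau_decay_ms", "tau_off_ms")) {
      st <- aggregate_stat(kinetics[[v]][kinetics$construct == cn],
                           kinetics[[v]][kinetics$construct == "WT"])
      comp <- rbind(comp, data.frame(construct = cn, quantity = v,
                                     mean = st$mean, sem = st$sem,
                                     n = st$n, p_vs_WT = st$comparison_p))
    }
  }

  report <- structure(list(
    kinetics = kinetics, normalized = normalized, erev = erev,
    delta_erev = delta, permeability = perm, pore = pore,
    pore_fits = pore_fits, comparisons = comp,
    config = list(T_K = T_K, basis = basis, kinetics_mV = kinetics_mV,
                  steady_window_ms = steady_window_ms,
                  test = "Welch two-sided t vs WT, uncorrected")
  ), class = "study_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in c("kinetics", "normalized", "erev", "delta_erev",
                 "permeability", "pore", "comparisons")) {
      if (!is.null(report[[nm]]))
        utils::write.csv(report[[nm]],
                         file.path(out_dir, paste0(nm, ".csv")),
                         row.names = FALSE)
    }
    jsonlite::write_json(
      report[c("kinetics", "normalized", "erev", "delta_erev",
               "permeability", "pore", "config")],
      file.path(out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows", pretty = TRUE)
  }
  report
}
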