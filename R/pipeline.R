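## One-config orchestration of the full analysis, plus replica handling.

#' Concatenate trajectory replicas
#'
#' Frames are concatenated in the given order; the start frame of every
#' replica after the first is recorded in the `boundaries` attribute so
#' that lag-based analyses ([cross_correlation()]) can exclude frame
#' pairs that straddle a replica boundary.
#'
#' @param trajs list of [trajectory_ensemble()] with matching atom
#'   counts and time steps
#' @return a [trajectory_ensemble()] with attribute `boundaries`
#' @export
replicate_concat <- function(trajs) {
  stopifnot(is.list(trajs), length(trajs) >= 1L)
  if (length(trajs) == 1L) return(trajs[[1L]])
  na <- vapply(trajs, function(t) dim(t$coords)[2], integer(1))
  dts <- vapply(trajs, function(t) t$dt, numeric(1))
  if (length(unique(na)) != 1L)
    stop("replicas have different atom counts: ",
         paste(unique(na), collapse = ", "))
  if (max(abs(diff(dts))) > 1e-12)
    stop("replicas have different time steps")
  nf <- vapply(trajs, n_frames, integer(1))
  co <- array(0, c(sum(nf), na[1L], 3L))
  off <- 0L
  for (t in trajs) {
    co[off + seq_len(n_frames(t)), , ] <- t$coords
    off <- off + n_frames(t)
  }
  out <- trajectory_ensemble(co, dt = dts[1L],
                             topology = trajs[[1L]]$topology)
  attr(out, "boundaries") <- cumsum(nf)[-length(nf)] + 1L
  out
}

## FNV-1a hash of a string, reported as hex (config provenance)
.fnv1a <- function(s) {
  ## 32-bit FNV-1a in doubles; 16-bit split keeps products exact
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    lo <- bitwXor(h %% 65536, b)
    hi <- h %/% 65536
    h <- (((hi * 16777619) %% 65536) * 65536 + lo * 16777619) %%
      4294967296
  }
  paste0(sprintf("%04x", as.integer(h %/% 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}

#' Assemble and validate a pipeline configuration
#'
#' Exactly one input source must be given: `trajectory` +
#' `structure` file paths, or a synthetic generator spec
#' (a [two_state_opener_spec()] or [gaussian_ensemble_spec()]). All
#' selections are resolved before any computation starts, so a typo
#' fails fast.
#'
#' @param structure PDB file for topology/reference (file input mode)
#' @param trajectory trajectory file(s), concatenated as replicas
#' @param synthetic a generator spec (synthetic mode)
#' @param selection analysis selection (default `"calpha"`)
#' @param pairs named list of length-2 character vectors: distance
#'   pairs as selection strings, e.g.
#'   `list(groove = c("resid 53 and name CA", "resid 220 and name CA"))`
#' @param reference_pair name in `pairs` used as the coupling reference
#'   (default the first pair)
#' @param cutoff contact cutoff, Angstrom (default 6)
#' @param fraction persistence fraction (default 0.3)
#' @param max_lag coupling max lag, frames (default `n/4` at run time)
#' @param n_components PCA components to report (default 10)
#' @param fel_bins,temperature landscape binning and temperature
#' @param dt frame time override, ns
#' @param seed RNG seed for synthetic inputs
#' @param output_dir directory for TSV/JSON artifacts (optional;
#'   nothing is written when `NULL`)
#' @return class `"pipeline_config"` (a validated list)
#' @export
pipeline_config <- function(structure = NULL, trajectory = NULL,
                            synthetic = NULL, selection = "calpha",
                            pairs = NULL, reference_pair = NULL,
                            cutoff = 6, fraction = 0.3, max_lag = NULL,
                            n_components = 10L, fel_bins = 64L,
                            temperature = 300, dt = NULL, seed = 1L,
                            output_dir = NULL) {
  file_mode <- !is.null(trajectory) || !is.null(structure)
  if (file_mode == !is.null(synthetic))
    stop("exactly one of (structure+trajectory, synthetic) must be given")
  if (file_mode && (is.null(trajectory) || is.null(structure)))
    stop("file input needs both a structure and a trajectory")
  if (!is.null(pairs)) {
    stopifnot(is.list(pairs), all(lengths(pairs) == 2L))
    if (is.null(names(pairs)))
      names(pairs) <- paste0("pair", seq_along(pairs))
    if (is.null(reference_pair)) reference_pair <- names(pairs)[1L]
    if (!reference_pair %in% names(pairs))
      stop("reference_pair '", reference_pair, "' not among pairs")
  }
  structure(list(structure = structure, trajectory = trajectory,
                 synthetic = synthetic, selection = selection,
                 pairs = pairs, reference_pair = reference_pair,
                 cutoff = cutoff, fraction = fraction,
                 max_lag = max_lag, n_components = as.integer(n_components),
                 fel_bins = as.integer(fel_bins),
                 temperature = temperature, dt = dt,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "pipeline_config")
}

.pipeline_inputs <- function(config) {
  if (!is.null(config$synthetic)) {
    spec <- config$synthetic
    spec$seed <- config$seed
    if (inherits(spec, "two_state_opener_spec")) {
      sim <- simulate_two_state_opener(spec)
      traj <- sim$traj
      pairs <- config$pairs
      if (is.null(pairs))
        pairs <- list(groove = c("resid 2 and name CA",
                                 "resid 1 and name CA"),
                      gate = c("resid 3 and name CA",
                               "resid 4 and name CA"))
      list(traj = traj, reference = frame_coords(traj, 1L),
           pairs = pairs, sim = sim)
    } else if (inherits(spec, "gaussian_ensemble_spec")) {
      traj <- sample_gaussian_ensemble(spec)
      list(traj = traj, reference = spec$mean, pairs = config$pairs,
           sim = NULL)
    } else stop("unknown synthetic spec of class ",
                paste(class(spec), collapse = "/"))
  } else {
    st <- read_structure(config$structure)
    paths <- config$trajectory
    trajs <- lapply(paths, read_trajectory, topology = st$topology,
                    dt = if (is.null(config$dt)) 1 else config$dt)
    traj <- replicate_concat(trajs)
    list(traj = traj, reference = frame_coords(st$traj, 1L),
         pairs = config$pairs, sim = NULL)
  }
}

#' Run the full groove-opening analysis pipeline
#'
#' Stages, in the order the science builds: distance series and
#' histogram summaries for every configured pair; the
#' persistence-gated correlation network and its shortest path map;
#' lagged cross-correlation of every pair against the reference pair
#' with event ordering; essential-dynamics PCA with cumulative variance
#' and cosine contents; and the PC1/PC2 free-energy landscape with
#' minima and representative frames. Deterministic given the seed; with
#' `output_dir` set, every table is also written as TSV/JSON together
#' with a provenance manifest (config hash, package and R versions).
#' Any stage failure aborts with the stage name; artifacts already
#' written are preserved.
#'
#' @param config a [pipeline_config()]
#' @return class `"pipeline_report"`: list with `distances`,
#'   `histograms`, `network` (`correlation`, `persistence`, `spm`),
#'   `coupling` (`ccf`, `events`), `ed` (`model`, `projections`,
#'   `cumulative_variance`, `cosine_content`), `landscape` (`surface`,
#'   `minima`, `representatives`), and `provenance`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$output_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ",
           conditionMessage(e), call. = FALSE))
  }
  inp <- stage("input", .pipeline_inputs(config))
  traj <- inp$traj
  top <- traj$topology
  ## pre-flight: every selection must resolve before computing anything
  sel <- stage("preflight", select_atoms(top, config$selection))
  pair_sel <- stage("preflight", lapply(inp$pairs, function(p)
    list(a = select_atoms(top, p[1L]), b = select_atoms(top, p[2L]))))
  boundaries <- attr(traj, "boundaries")
  report <- list()

  report$distances <- stage("distances", lapply(pair_sel, function(p)
    distance_series(traj, p$a, p$b)))
  report$histograms <- stage("histograms", lapply(report$distances,
    function(d) tryCatch(summarize_histogram(d),
                         error = function(e) NULL)))

  report$network <- stage("network", {
    ref <- inp$reference
    C <- displacement_correlation(traj, sel, ref,
                                  fit = is.null(inp$sim))
    P <- contact_persistence(traj, sel, config$cutoff)
    g <- build_graph(C, P, config$fraction)
    list(correlation = C, persistence = P, graph = g,
         spm = shortest_path_map(g))
  })

  report$coupling <- stage("coupling", {
    if (length(report$distances) >= 2L) {
      refp <- config$reference_pair
      if (is.null(refp)) refp <- names(report$distances)[1L]
      ml <- config$max_lag
      if (is.null(ml)) ml <- floor(n_frames(traj) / 4)
      others <- report$distances[setdiff(names(report$distances), refp)]
      ccs <- lapply(others, cross_correlation,
                    y = report$distances[[refp]], max_lag = ml,
                    boundaries = boundaries)
      list(reference = refp, ccf = ccs,
           events = event_order(others, report$distances[[refp]], ml,
                                boundaries = boundaries))
    } else NULL
  })

  report$ed <- stage("essential dynamics", {
    if (n_frames(traj) < 10L)
      warning("only ", n_frames(traj),
              " frames: PCA eigenvalues will be poorly determined")
    model <- fit_ed(traj, sel, inp$reference, fit = is.null(inp$sim),
                    n_components = config$n_components)
    k <- min(5L, length(model$eigenvalues))
    proj <- project_ed(traj, model, k = k)
    list(model = model, projections = proj,
         cumulative_variance = cumulative_variance(model),
         cosine_content = vapply(seq_len(k), function(i)
           cosine_content(proj, i), numeric(1)))
  })

  report$landscape <- stage("free-energy landscape", {
    surf <- fel(report$ed$projections, bins = config$fel_bins,
                temperature = config$temperature)
    mins <- find_minima(surf)
    list(surface = surf, minima = mins,
         representatives = representative_frames(report$ed$projections,
                                                 mins))
  })

  report$provenance <- list(
    config_hash = .fnv1a(jsonlite::toJSON(
      config[!vapply(config, is.object, logical(1))],
      auto_unbox = TRUE, null = "null", force = TRUE)),
    package = as.character(packageVersion("groovedyn")),
    r_version = R.version.string,
    seed = config$seed,
    n_frames = n_frames(traj),
    timestamp = format(Sys.time(), tz = "UTC"))
  class(report) <- "pipeline_report"
  if (!is.null(out_dir)) .write_report(report, out_dir)
  report
}

.write_report <- function(report, dir) {
  tsv <- function(df, f) write.table(df, file.path(dir, f), sep = "\t",
                                     quote = FALSE, row.names = FALSE)
  dist_df <- data.frame(
    frame = seq_along(report$distances[[1L]]$values),
    time_ns = (seq_along(report$distances[[1L]]$values) - 1L) *
      report$distances[[1L]]$dt)
  for (nm in names(report$distances))
    dist_df[[nm]] <- report$distances[[nm]]$values
  tsv(dist_df, "distances.tsv")
  hs <- report$histograms[!vapply(report$histograms, is.null, logical(1))]
  jsonlite::write_json(
    lapply(hs, function(h) list(mean = h$mean, sd = h$sd,
                                band2sigma = h$band2sigma,
                                quantiles = as.list(h$quantiles),
                                peaks = h$peaks)),
    file.path(dir, "histograms.json"), auto_unbox = TRUE, digits = NA)
  write_spm_tsv(report$network$spm, file.path(dir, "spm_edges.tsv"))
  tsv(data.frame(residue = names(report$network$spm$node_usage),
                 usage = as.numeric(report$network$spm$node_usage)),
      "spm_nodes.tsv")
  if (!is.null(report$coupling)) {
    for (nm in names(report$coupling$ccf)) {
      cc <- report$coupling$ccf[[nm]]
      tsv(data.frame(lag_frames = cc$lags, lag_ns = cc$lag_ns, r = cc$r),
          paste0("ccf_", gsub("[^A-Za-z0-9_.-]", "_", nm), ".tsv"))
    }
    tsv(as.data.frame(report$coupling$events), "event_order.tsv")
  }
  tsv(data.frame(pc = seq_along(report$ed$cumulative_variance),
                 eigenvalue = report$ed$model$eigenvalues[
                   seq_along(report$ed$cumulative_variance)],
                 cumulative_variance = report$ed$cumulative_variance),
      "ed_spectrum.tsv")
  proj_df <- as.data.frame(report$ed$projections$proj)
  proj_df <- cbind(frame = seq_len(nrow(proj_df)), proj_df)
  tsv(proj_df, "ed_projections.tsv")
  tsv(data.frame(pc = seq_along(report$ed$cosine_content),
                 cosine_content = report$ed$cosine_content),
      "ed_cosine_content.tsv")
  mins <- report$landscape$minima
  mins$frame <- report$landscape$representatives
  tsv(mins, "fel_minima.tsv")
  en <- report$landscape$surface$energy
  tsv(as.data.frame(en), "fel_energy.tsv")
  jsonlite::write_json(report$provenance,
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("groove-opening pipeline report\n")
  cat("  pairs:", paste(names(x$distances), collapse = ", "), "\n")
  if (!is.null(x$coupling)) {
    cat("  coupling vs '", x$coupling$reference, "':\n", sep = "")
    ev <- x$coupling$events
    for (i in seq_len(nrow(ev)))
      cat(sprintf("    %s: r* = %.3f at lag %d frames%s\n", ev$name[i],
                  ev$r[i], ev$lag[i],
                  if (ev$significant[i]) "" else " (not significant)"))
  }
  cv <- x$ed$cumulative_variance
  cat("  PC1+PC2 capture", round(100 * cv[min(2L, length(cv))], 1),
      "% of variance; cosine contents:",
      paste(signif(x$ed$cosine_content, 3), collapse = ", "), "\n")
  cat("  FEL minima:", nrow(x$landscape$minima), "(energies",
      paste(round(x$landscape$minima$energy, 2), collapse = ", "),
      "kJ/mol)\n")
  cat("  config hash:", x$provenance$config_hash, "\n")
  invisible(x)
}
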