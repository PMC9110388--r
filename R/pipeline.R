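# Orchestration of the four-stage integrative workflow: (1) gather a model
# and reference structures, (2) sample additional conformational states by
# metadynamics, (3) score them on the free-energy surface and bin
# microstates, (4) validate the multi-state picture against (synthetic)
# SAXS data.  Also: a geometry report comparing crystallographic
# conformational states.

#' Configuration for the integrative demo
#'
#' A flat key/value configuration; every stochastic stage derives its seed
#' from `seed`, so a fixed configuration reproduces the report bit for bit.
#'
#' @param seed master seed (integer)
#' @param n_steps metadynamics steps (default 5e6)
#' @param weights generating population weights for the 3-state synthetic
#'   experiment (EM2/EM3/EM4 representatives)
#' @param noise_a relative noise level of the synthetic experiment
#' @param equilibration_fraction fraction of the run discarded as
#'   equilibration
#' @param k_max largest multi-state model considered
#' @return named list of class `run_config`
#' @export
demo_config <- function(seed = 1, n_steps = 5e6,
                        weights = c(0.607, 0.314, 0.079),
                        noise_a = 0.01, equilibration_fraction = 0.2,
                        k_max = 3) {
  structure(list(seed = as.integer(seed), n_steps = n_steps,
                 weights = weights, noise_a = noise_a,
                 equilibration_fraction = equilibration_fraction,
                 k_max = k_max),
            class = "run_config")
}

#' Serialise / parse a flat configuration as key = value text
#' @param config a `run_config`
#' @param path file path
#' @return `read_config` returns a `run_config`
#' @export
write_config <- function(config, path) {
  lines <- vapply(names(config), function(nm)
    sprintf("%s = %s", nm, paste(format(config[[nm]], digits = 17),
                                 collapse = " ")), "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  out <- list()
  for (ln in lines[nzchar(trimws(lines))]) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    vals <- strsplit(trimws(kv[2]), "[[:space:]]+")[[1]]
    num <- suppressWarnings(as.numeric(vals))
    out[[key]] <- if (anyNA(num)) vals else num
  }
  out$seed <- as.integer(out$seed)
  structure(out, class = "run_config")
}

.config_hash <- function(config) {
  txt <- paste(names(config),
               vapply(config, function(v) paste(format(v, digits = 17),
                                                collapse = ","), ""),
               collapse = ";")
  # small rolling hash; enough to tag outputs with their configuration
  h <- 0
  for (ch in utf8ToInt(txt)) h <- (h * 131 + ch) %% 2147483647
  sprintf("%08x", h)
}

#' Run the integrative demonstration pipeline
#'
#' Executes the full workflow on the synthetic pincer: build the
#' `abna-landscape` model; run metadynamics; reconstruct the free-energy
#' surface and its convergence diagnostics; bin microstates and extract
#' representative conformers for the landscape wells; synthesise a noisy
#' 3-state SAXS experiment from the EM2/EM3/EM4 representatives with the
#' configured population weights; fit multi-state models to it; and report
#' recovered well free energies, recovered weights and the
#' population-weighted mean Rg.
#'
#' @param config a [demo_config()]
#' @param out_dir optional directory for per-stage artifacts (hills, FES,
#'   profiles, report text); created if missing
#' @return object of class `pincer_report`
#' @export
run_integrative_demo <- function(config = demo_config(), out_dir = NULL) {
  t0 <- Sys.time()
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  stage <- "gather"
  art <- list()
  persist <- function() {
    if (is.null(out_dir)) return(invisible())
    if (!is.null(art$bias)) write_hills(art$bias, file.path(out_dir, "hills.txt"))
    if (!is.null(art$experiment)) write_saxs(art$experiment,
                                             file.path(out_dir, "experiment.dat"))
    write_config(config, file.path(out_dir, "config.txt"))
  }
  res <- tryCatch({
    model <- build_pincer()
    art$model <- model

    stage <- "sample"
    run <- metad_run(model, n_steps = config$n_steps,
                     seed = config$seed, cv_stride = 100,
                     frame_stride = 1000)
    art$traj <- run$traj; art$bias <- run$bias

    stage <- "score"
    equil_t <- config$equilibration_fraction * max(run$traj$time)
    fes <- fes_from_bias(run$bias)
    conv <- convergence_report(run$traj, run$bias, equilibration_time = equil_t)
    if (!all(conv$converged))
      warning("metadynamics not converged at all tolerances", call. = FALSE)
    micro <- bin_microstates(run$traj, fes, equilibration = equil_t)
    ddg <- fes_well_ddg(fes, model$wells)
    names(ddg) <- model$wells$name
    # representative conformer per well: stored frame nearest the well center
    reps <- lapply(seq_len(nrow(model$wells)), function(k) {
      dist2 <- ((micro$d - model$wells$d[k]) / model$wells$sigma_d[k])^2 +
        (.wrap((micro$phi - model$wells$phi[k]) * pi / 180) /
           (model$wells$sigma_phi[k] * pi / 180))^2
      cand <- order(dist2)
      cand <- cand[!is.na(micro$representative[cand])]
      if (!length(cand)) return(NULL)
      frame_structure(run$traj, micro$representative[cand[1]])
    })
    names(reps) <- model$wells$name
    art$fes <- fes; art$microstates <- micro; art$representatives <- reps

    stage <- "validate"
    if (any(vapply(reps, is.null, TRUE)))
      stop("missing representative conformer for well(s): ",
           paste(model$wells$name[vapply(reps, is.null, TRUE)], collapse = ", "))
    gen_states <- c("EM2", "EM3", "EM4")
    mix <- mixture_spec(reps[gen_states], config$weights,
                        noise_a = config$noise_a)
    experiment <- synthetic_saxs_experiment(mix, seed = config$seed + 1000L,
                                            bead_radius = model$bead_radius)
    art$experiment <- experiment
    cand_profiles <- lapply(reps, debye_profile,
                            bead_radius = model$bead_radius)
    fit <- multistate_fit(experiment, cand_profiles, k_max = config$k_max)
    sel <- select_k(fit)
    # recovered vs generating weights, matched by candidate identity
    truth <- setNames(rep(0, length(reps)), names(reps))
    truth[gen_states] <- config$weights
    recovered <- setNames(rep(0, length(reps)), names(reps))
    recovered[names(reps)[sel$states]] <- sel$weights
    weight_rmse <- sqrt(mean((recovered - truth)^2))
    rgs <- vapply(reps, radius_of_gyration, 0.0)
    wrg <- ensemble_rg(rgs[sel$states], sel$weights / sum(sel$weights))
    guinier <- guinier_fit(experiment)

    report <- structure(list(
      config = config, config_hash = .config_hash(config),
      ddg = ddg, convergence = conv,
      n_microstates = nrow(micro),
      n_contiguous = sum(micro$contiguous),
      fit = fit, selected = sel,
      recovered_weights = recovered, generating_weights = truth,
      weight_rmse = weight_rmse,
      state_rg = rgs, weighted_rg = wrg,
      guinier_rg = guinier$Rg,
      manifest = list(seed = config$seed,
                      package_version = as.character(utils::packageVersion("pincerflex")),
                      r_version = R.version.string,
                      elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
      artifacts = art), class = "pincer_report")
    persist()
    if (!is.null(out_dir)) {
      txt <- utils::capture.output(print(report))
      writeLines(txt, file.path(out_dir, "report.txt"))
    }
    report
  }, error = function(e) {
    persist()
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  res
}

#' @export
print.pincer_report <- function(x, ...) {
  cat("Integrative pipeline report (config", x$config_hash, ")\n")
  cat(sprintf("  seed %d, %g metadynamics steps\n", x$config$seed, x$config$n_steps))
  cat(sprintf("  microstates: %d (%d contiguous)\n", x$n_microstates, x$n_contiguous))
  cat("  recovered well ddG (kcal/mol):",
      paste(sprintf("%s=%.2f", names(x$ddg), x$ddg), collapse = ", "), "\n")
  cat(sprintf("  max |dF| late checkpoints: %.2f kcal/mol\n",
              x$convergence$max_delta_f))
  cat(sprintf("  multi-state fit: k = %d selected, chi = %.3f\n",
              x$selected$k, x$selected$chi))
  cat("  recovered weights:",
      paste(sprintf("%s=%.1f%%", names(x$recovered_weights),
                    100 * x$recovered_weights), collapse = ", "), "\n")
  cat(sprintf("  weight RMSE vs generating mixture: %.4f\n", x$weight_rmse))
  cat(sprintf("  population-weighted Rg: %.1f A (Guinier Rg of the synthetic experiment: %.1f A)\n",
              x$weighted_rg, x$guinier_rg))
  invisible(x)
}

.pair_atoms <- function(a, b, atom_name = NULL) {
  if (!is.null(atom_name)) {
    a_idx <- which(a$name == atom_name); b_idx <- which(b$name == atom_name)
  } else {
    a_idx <- seq_len(nrow(a)); b_idx <- seq_len(nrow(b))
  }
  ka <- paste(a$chain[a_idx], a$resno[a_idx], a$name[a_idx])
  kb <- paste(b$chain[b_idx], b$resno[b_idx], b$name[b_idx])
  common <- intersect(ka, kb)
  cbind(a_idx[match(common, ka)], b_idx[match(common, kb)])
}

#' Geometry report for a set of conformational states
#'
#' For each structure: the collective-variable pair, the radius of gyration
#' and (optionally) the buried area between the first two domains.  For
#' each ordered pair of structures: the RMSD after superposing on Domain1,
#' the maximum displacement of paired Domain4 atoms after that alignment,
#' and the internal rotation angle of Domain4 (the rotation of the
#' Domain4-only superposition applied after the global Domain1 alignment).
#'
#' @param structures list of structures (or character vector of PDB paths);
#'   names are used as state labels
#' @param partition a [domain_partition()] (>= 4 domains)
#' @param atom_name atom used for pairing and superposition (default
#'   `"CA"`; coarse-grained beads fall back to all atoms automatically)
#' @param buried_area compute the Domain1-Domain2 buried interface area
#'   (Shrake-Rupley; the slowest part for atomic models)
#' @param sasa_points sphere points per atom for the buried-area computation
#' @return list with `states` (per-structure data.frame) and `pairs`
#'   (pairwise data.frame), class `crystal_geometry_report`
#' @export
crystal_geometry_report <- function(structures, partition = abna_partition(),
                                    atom_name = "CA", buried_area = TRUE,
                                    sasa_points = 240) {
  if (is.character(structures)) {
    paths <- structures
    structures <- lapply(paths, read_structure)
    names(structures) <- sub("\\.pdb$", "", basename(paths), ignore.case = TRUE)
  }
  if (is.null(names(structures)))
    names(structures) <- paste0("state", seq_along(structures))
  for (s in structures) {
    miss <- vapply(seq_len(nrow(partition)), function(k)
      !any(s$resno >= partition$first[k] & s$resno <= partition$last[k]), TRUE)
    if (any(miss))
      stop("partition unresolvable: no atoms in ",
           paste(partition$name[miss], collapse = ", "), call. = FALSE)
  }
  states <- do.call(rbind, lapply(names(structures), function(nm) {
    s <- structures[[nm]]
    cv <- cv_pair(s, partition)
    ba <- if (buried_area)
      buried_interface_area(s,
                            c(partition$first[1], partition$last[1]),
                            c(partition$first[2], partition$last[2]),
                            n_points = sasa_points) else NA_real_
    data.frame(state = nm, d = cv$d, phi = cv$phi,
               rg = radius_of_gyration(s), buried_d1d2 = ba,
               n_atoms = nrow(s), stringsAsFactors = FALSE)
  }))
  pick_name <- function(s) if (any(s$name == atom_name)) atom_name else NULL
  pairs <- list()
  nms <- names(structures)
  if (length(nms) > 1) {
    for (i in seq_along(nms)) for (j in seq_along(nms)) {
      if (i == j) next
      a <- structures[[nms[i]]]; b <- structures[[nms[j]]]
      an <- pick_name(a)
      pr_all <- .pair_atoms(a, b, an)
      in_dom <- function(res, k) res >= partition$first[k] & res <= partition$last[k]
      pr_d1 <- pr_all[in_dom(a$resno[pr_all[, 1]], 1), , drop = FALSE]
      pr_d4 <- pr_all[in_dom(a$resno[pr_all[, 1]], 4), , drop = FALSE]
      if (nrow(pr_d1) < 3 || nrow(pr_d4) < 3) next
      sup1 <- superpose(a, b, pairing = pr_d1)
      moved <- sup1$mobile_fitted
      rmsd_all <- sqrt(mean(rowSums((moved[pr_all[, 1], ] -
                                       coords(b)[pr_all[, 2], ])^2)))
      disp4 <- sqrt(rowSums((moved[pr_d4[, 1], ] -
                               coords(b)[pr_d4[, 2], ])^2))
      sup4 <- superpose(moved[pr_d4[, 1], , drop = FALSE],
                        coords(b)[pr_d4[, 2], , drop = FALSE])
      pairs[[length(pairs) + 1]] <- data.frame(
        mobile = nms[i], reference = nms[j],
        rmsd_after_d1 = rmsd_all,
        d4_max_displacement = max(disp4),
        d4_mean_displacement = mean(disp4),
        d4_rotation = rotation_angle(sup4$rotation),
        n_paired = nrow(pr_all), stringsAsFactors = FALSE)
    }
  }
  structure(list(states = states,
                 pairs = if (length(pairs)) do.call(rbind, pairs) else NULL),
            class = "crystal_geometry_report")
}

#' @export
print.crystal_geometry_report <- function(x, ...) {
  cat("Conformational-state geometry:\n")
  print(x$states, row.names = FALSE, digits = 4)
  if (!is.null(x$pairs)) {
    cat("Pairwise (after Domain1 alignment):\n")
    print(x$pairs, row.names = FALSE, digits = 4)
  }
  invisible(x)
}
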