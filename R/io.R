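#' Write a trajectory as (multi-frame) XYZ
#'
#' Species-encoded element column (`RH`/`BH` for heads, `RT`/`BT` for
#' tails); coordinates in nm (noted in the comment line together with the
#' frame time and box edge).
#'
#' @param traj an `mcg_trajectory`.
#' @param file output path.
#' @export
write_xyz <- function(traj, file) {
  el <- c("RH", "BH", "RT", "BT")[traj$type]
  con <- file(file, "w")
  on.exit(close(con))
  for (k in seq_along(traj$frames)) {
    p <- traj$frames[[k]]
    writeLines(as.character(nrow(p)), con)
    writeLines(sprintf("t=%.6f ns units=nm box=%.5f", traj$times[k], traj$box), con)
    writeLines(sprintf("%s %12.6f %12.6f %12.6f", el, p[, 1], p[, 2], p[, 3]), con)
  }
  invisible(file)
}

#' Read a (multi-frame) XYZ trajectory
#'
#' Coordinates are taken as nm. The comment line is scanned for `t=` and
#' `box=` tags (as written by [write_xyz()]); a missing box must be
#' supplied via `box`.
#'
#' @param file XYZ path.
#' @param box cubic box edge (nm) when absent from the file.
#' @param atoms_per_mol beads per molecule, to reconstruct molecule ids.
#' @return trajectory-like list (`frames`, `times`, `box`, `mol_id`,
#'   `element`).
#' @export
read_xyz <- function(file, box = NULL, atoms_per_mol = 5L) {
  lines <- readLines(file)
  frames <- list(); times <- numeric(0); elements <- NULL
  i <- 1L; k <- 0L; n0 <- NA_integer_
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("malformed XYZ: bad atom count at line ", i)
    if (is.na(n0)) n0 <- n
    if (n != n0) stop("XYZ frames have varying atom counts (frame ", k + 1L, ")")
    cmt <- lines[i + 1L]
    tm <- regmatches(cmt, regexpr("t=([0-9eE.+-]+)", cmt))
    bx <- regmatches(cmt, regexpr("box=([0-9eE.+-]+)", cmt))
    rows <- lines[i + 1L + seq_len(n)]
    parts <- strsplit(trimws(rows), "\\s+")
    bad <- which(vapply(parts, length, integer(1)) < 4)
    if (length(bad)) stop("corrupt XYZ frame ", k + 1L, " near atom ", bad[1])
    m <- matrix(as.numeric(unlist(lapply(parts, `[`, 2:4))), n, 3, byrow = TRUE)
    if (anyNA(m)) stop("corrupt coordinates in XYZ frame ", k + 1L)
    k <- k + 1L
    frames[[k]] <- m
    times[k] <- if (length(tm)) as.numeric(sub("t=", "", tm)) else k - 1
    if (is.null(elements)) elements <- vapply(parts, `[`, "", 1L)
    if (is.null(box) && length(bx)) box <- as.numeric(sub("box=", "", bx))
    i <- i + 2L + n
  }
  if (is.null(box)) stop("box edge not found in file; pass box=")
  list(frames = frames, times = times, box = box,
       mol_id = rep(seq_len(n0 / atoms_per_mol), each = atoms_per_mol)[seq_len(n0)],
       element = elements)
}

#' Write a trajectory as (multi-frame) GRO
#'
#' Fixed-format GRO frames concatenated in one file; positions in nm, one
#' residue per molecule (residue names `RSU`/`BSU` by species), cubic box
#' line per frame, frame time (ps) in the title.
#'
#' @param traj an `mcg_trajectory`.
#' @param file output path.
#' @export
write_gro <- function(traj, file) {
  atom_names <- c(head = "H", tail1 = "T1", tail2 = "T2",
                  tail3 = "T3", tail4 = "T4")[traj$role]
  resname <- ifelse(traj$species[traj$mol_id] == "R", "RSU", "BSU")
  con <- file(file, "w")
  on.exit(close(con))
  n <- length(traj$mol_id)
  for (k in seq_along(traj$frames)) {
    p <- traj$frames[[k]]
    writeLines(sprintf("mCG micelle t= %.5f", traj$times[k] * 1e3), con)
    writeLines(sprintf("%5d", n), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       traj$mol_id %% 100000L, resname, atom_names,
                       seq_len(n) %% 100000L, p[, 1], p[, 2], p[, 3]), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", traj$box, traj$box, traj$box), con)
  }
  invisible(file)
}

#' Read a (multi-frame) GRO trajectory
#'
#' @param file GRO path.
#' @return trajectory-like list (`frames`, `times` ns, `box`, `mol_id`,
#'   `resname`, `atom_name`).
#' @export
read_gro <- function(file) {
  lines <- readLines(file)
  frames <- list(); times <- numeric(0); box <- NA_real_
  mol_id <- NULL; resname <- NULL; atom_name <- NULL
  i <- 1L; k <- 0L; n0 <- NA_integer_
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    title <- lines[i]
    n <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(n)) stop("malformed GRO: bad atom count at line ", i + 1L)
    if (is.na(n0)) n0 <- n
    if (n != n0) stop("GRO frames have varying atom counts (frame ", k + 1L, ")")
    rows <- lines[i + 1L + seq_len(n)]
    x <- as.numeric(substr(rows, 21, 28))
    y <- as.numeric(substr(rows, 29, 36))
    z <- as.numeric(substr(rows, 37, 44))
    if (anyNA(x) || anyNA(y) || anyNA(z))
      stop("corrupt coordinates in GRO frame ", k + 1L)
    boxline <- strsplit(trimws(lines[i + 2L + n]), "\\s+")[[1]]
    bx <- as.numeric(boxline[1])
    tm <- regmatches(title, regexpr("t=\\s*([0-9eE.+-]+)", title))
    k <- k + 1L
    frames[[k]] <- cbind(x, y, z)
    times[k] <- if (length(tm)) as.numeric(sub("t=\\s*", "", tm)) * 1e-3 else k - 1
    if (k == 1L) {
      mol_id <- as.integer(substr(rows, 1, 5))
      mol_id <- cumsum(c(TRUE, diff(mol_id) != 0))
      resname <- trimws(substr(rows, 6, 10))
      atom_name <- trimws(substr(rows, 11, 15))
      box <- bx
    }
    i <- i + 3L + n
  }
  list(frames = frames, times = times, box = box, mol_id = mol_id,
       resname = resname, atom_name = atom_name)
}

#' Read a trajectory from standard files
#'
#' Dispatches on format (`"gro"` or `"xyz"`, guessed from the extension)
#' and attaches an optional head map so that the result can feed
#' [build_soap_dataset()] directly. When the head map carries species
#' labels they are attached per molecule.
#'
#' @param path trajectory file.
#' @param format `"gro"`, `"xyz"` or `"auto"`.
#' @param head_map optional head-map data.frame or CSV path (columns
#'   `molecule`, `species`, `heads` with 0-based ";"-separated indices).
#' @param box box edge for XYZ files lacking a box tag.
#' @return trajectory-like list compatible with the analysis stages.
#' @export
read_trajectory <- function(path, format = c("auto", "gro", "xyz"),
                            head_map = NULL, box = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gro$", path, ignore.case = TRUE)) "gro" else "xyz"
  traj <- if (format == "gro") read_gro(path) else read_xyz(path, box = box)
  if (is.character(head_map)) head_map <- read_head_map(head_map)
  traj$head_map <- head_map
  if (!is.null(head_map))
    traj$species <- head_map$species[order(head_map$molecule)]
  else if (!is.null(traj$resname))
    traj$species <- ifelse(traj$resname[match(unique(traj$mol_id), traj$mol_id)] == "RSU",
                           "R", "B")
  # files written by this package (atom names H, T1..T4) carry enough
  # topology to restore the full trajectory layout
  if (!is.null(traj$atom_name) &&
      all(traj$atom_name %in% c("H", "T1", "T2", "T3", "T4")) &&
      all(table(traj$mol_id) == 5L)) {
    traj$role <- c(H = "head", T1 = "tail1", T2 = "tail2",
                   T3 = "tail3", T4 = "tail4")[traj$atom_name]
    names(traj$role) <- NULL
    n_mol <- length(unique(traj$mol_id))
    traj$type <- ifelse(traj$species[traj$mol_id] == "R", 1L, 2L)
    traj$type[traj$role != "head"] <- traj$type[traj$role != "head"] + 2L
    traj$bonds <- do.call(rbind, lapply(seq_len(n_mol), function(m) {
      b <- (m - 1L) * 5L
      cbind(b + 1:4, b + 2:5)
    }))
    class(traj) <- "mcg_trajectory"
  }
  traj
}

#' Read / write a head map
#'
#' CSV with columns `molecule` (1-based molecule id), `species`, `heads`
#' (0-based bead indices within the molecule, ";"-separated).
#'
#' @param file CSV path.
#' @return data.frame head map.
#' @export
read_head_map <- function(file) {
  hm <- read.csv(file, stringsAsFactors = FALSE)
  req <- c("molecule", "species", "heads")
  if (!all(req %in% names(hm))) stop("head map needs columns: ", paste(req, collapse = ", "))
  hm
}

#' @rdname read_head_map
#' @param head_map data.frame to write.
#' @export
write_head_map <- function(head_map, file) {
  write.csv(head_map, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Write the per-frame simulation log
#'
#' CSV of time (ns), potential energy (kJ/mol) and instantaneous kinetic
#' temperature (K) per sampled frame.
#'
#' @param traj an `mcg_trajectory`.
#' @param file CSV path.
#' @export
write_sim_log <- function(traj, file) {
  write.csv(traj$log, file, row.names = FALSE)
  invisible(file)
}

# ---- pipeline ---------------------------------------------------------------

.pipeline_defaults <- list(
  sim = list(enabled = TRUE, n_R = 100L, n_B = 100L, regime = "mixing",
             sigma_R = 0.7, sigma_B = 0.7, mode = "preassembled_micelle",
             arrangement = "mixed", box = 20, temperature = 300, dt = 0.04,
             tau_t = 0.1, n_steps = 100000L, stride = 2500L,
             equilibration = 25000L, minimize_steps = 200L),
  input = list(trajectory = NULL, head_map = NULL, box = NULL),
  soap = list(cutoff = 30, units = "angstrom", n_max = 8L, l_max = 8L,
              sigma_atom = 3.5, species_policy = "single_channel",
              stride = 1L),
  pca = list(npc = 5L, variance_target = NULL),
  pamm = list(ngrid = 1500L, fs = 0.1, merge_threshold = 0.01),
  structure = list(rdf = TRUE, contacts = TRUE, rg = TRUE,
                   contact_cutoff = 0.8),
  output = list(prefix = "micellemotifs", dir = ".", write_xyz = FALSE),
  seed = 1L)

.merge_config <- function(user, defaults, path = "") {
  for (nm in names(user)) {
    if (!nm %in% names(defaults))
      stop("unknown configuration key: ", paste0(path, nm))
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      defaults[[nm]] <- .merge_config(user[[nm]], defaults[[nm]],
                                      paste0(path, nm, "/"))
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

#' Load and validate a pipeline configuration
#'
#' YAML file (or list) with sections `sim`, `input`, `soap`, `pca`,
#' `pamm`, `structure`, `output` and a global `seed`. Unknown keys are
#' rejected; missing keys take the documented defaults.
#'
#' @param config YAML path or list.
#' @return validated configuration list.
#' @export
load_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- .merge_config(config, .pipeline_defaults)
  stopifnot(cfg$pamm$ngrid >= 1, cfg$pamm$fs > 0,
            cfg$soap$n_max >= 1, cfg$soap$l_max >= 0)
  cfg
}

#' Run the full motif-reconstruction pipeline
#'
#' Simulate (optional) -> SOAP -> PCA -> PAMM -> interconversion diagrams
#' -> structural metrics, writing per-stage outputs (CSV/JSON/DOT) under
#' the configured prefix together with the resolved configuration and
#' seeds. Fully deterministic for a fixed configuration and seed.
#'
#' @param config YAML path or configuration list
#'   (see [load_pipeline_config()]).
#' @return report list with each stage's key results and output paths.
#' @export
run_pipeline <- function(config) {
  cfg <- load_pipeline_config(if (is.list(config)) config else config)
  dir.create(cfg$output$dir, showWarnings = FALSE, recursive = TRUE)
  pfx <- file.path(cfg$output$dir, cfg$output$prefix)
  out_files <- character(0)

  # stage 1: trajectory
  if (!is.null(cfg$input$trajectory)) {
    traj <- read_trajectory(cfg$input$trajectory, head_map = cfg$input$head_map,
                            box = cfg$input$box)
    head_map <- traj$head_map
  } else {
    if (!isTRUE(cfg$sim$enabled)) stop("stage sim: no trajectory given and simulation disabled")
    sc <- sim_config(box = cfg$sim$box, temperature = cfg$sim$temperature,
                     dt = cfg$sim$dt, tau_t = cfg$sim$tau_t,
                     n_steps = cfg$sim$n_steps, stride = cfg$sim$stride,
                     seed = cfg$seed)
    pt <- mcg_pair_table(cfg$sim$regime, sigma_R = cfg$sim$sigma_R,
                         sigma_B = cfg$sim$sigma_B)
    st <- build_bicomponent_system(cfg$sim$n_R, cfg$sim$n_B, pt, sc,
                                   mode = cfg$sim$mode,
                                   arrangement = cfg$sim$arrangement,
                                   seed = cfg$seed)
    traj <- run_simulation(st, pt, sc, equilibration = cfg$sim$equilibration,
                           minimize_steps = cfg$sim$minimize_steps,
                           seed = cfg$seed)
    head_map <- NULL
    write_sim_log(traj, paste0(pfx, "_simlog.csv"))
    out_files <- c(out_files, paste0(pfx, "_simlog.csv"))
    if (isTRUE(cfg$output$write_xyz)) {
      write_xyz(traj, paste0(pfx, "_traj.xyz"))
      out_files <- c(out_files, paste0(pfx, "_traj.xyz"))
    }
  }

  # stage 2: SOAP
  sp <- soap_params(r_cut = cfg$soap$cutoff, n_max = cfg$soap$n_max,
                    l_max = cfg$soap$l_max, sigma_atom = cfg$soap$sigma_atom,
                    species_policy = cfg$soap$species_policy,
                    units = cfg$soap$units)
  ds <- build_soap_dataset(traj, sp, head_map = head_map,
                           stride = cfg$soap$stride)

  # stage 3: PCA
  model <- fit_pca(ds, n_components = cfg$pca$npc,
                   variance_target = cfg$pca$variance_target)
  emb <- pca_transform(model, ds)
  scatter <- data.frame(PC1 = emb$Y[, 1],
                        PC2 = if (ncol(emb$Y) > 1) emb$Y[, 2] else NA_real_,
                        emb$meta)
  write.csv(scatter, paste0(pfx, "_embedding.csv"), row.names = FALSE)
  out_files <- c(out_files, paste0(pfx, "_embedding.csv"))

  # stage 4: PAMM
  cl <- pamm_cluster(emb, ngrid = cfg$pamm$ngrid, fs = cfg$pamm$fs,
                     merge_threshold = cfg$pamm$merge_threshold,
                     seed = cfg$seed)
  labs <- data.frame(ds$meta, cluster = cl$labels)
  write.csv(labs, paste0(pfx, "_labels.csv"), row.names = FALSE)
  out_files <- c(out_files, paste0(pfx, "_labels.csv"))

  # stage 5: interconversion diagrams
  series <- label_series(cl$labels, ds$meta, K = cl$model$K)
  diagram <- build_interconversion_diagram(series)
  write_interconversion_diagram(diagram,
                                json_file = paste0(pfx, "_diagram.json"),
                                dot_file = paste0(pfx, "_diagram.dot"))
  out_files <- c(out_files, paste0(pfx, "_diagram.json"), paste0(pfx, "_diagram.dot"))

  # stage 6: structural metrics (built-in trajectories only)
  structure_res <- NULL
  if (inherits(traj, "mcg_trajectory")) {
    structure_res <- list()
    if (isTRUE(cfg$structure$rdf)) {
      rdf <- rdf_head_core(traj)
      write.csv(rdf$df, paste0(pfx, "_rdf.csv"), row.names = FALSE)
      out_files <- c(out_files, paste0(pfx, "_rdf.csv"))
      structure_res$rdf_peak_nm <- rdf$df$r[which.max(rdf$df$g)]
    }
    if (isTRUE(cfg$structure$contacts)) {
      hR <- which(traj$role == "head" & traj$species[traj$mol_id] == "R")
      hB <- which(traj$role == "head" & traj$species[traj$mol_id] == "B")
      if (length(hR) && length(hB))
        structure_res$contacts_RB <- contact_count(
          lapply(traj$frames, function(p) p[hR, , drop = FALSE]),
          lapply(traj$frames, function(p) p[hB, , drop = FALSE]),
          cutoff = cfg$structure$contact_cutoff, box = traj$box)
    }
    if (isTRUE(cfg$structure$rg)) {
      lastp <- unwrap_aggregate(traj$frames[[length(traj$frames)]],
                                traj$bonds, traj$mol_id, traj$box)
      structure_res$gyration_radius_nm <- gyration_radius(lastp, box = NULL)
    }
  }

  provenance <- list(config = cfg, seed = cfg$seed,
                     package_version = as.character(utils::packageVersion("micellemotifs")),
                     n_soap_rows = nrow(ds$X))
  jsonlite::write_json(provenance, paste0(pfx, "_provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  out_files <- c(out_files, paste0(pfx, "_provenance.json"))

  list(config = cfg,
       trajectory = traj,
       soap = ds,
       pca = model,
       cluster_model = cl$model,
       K = cl$model$K,
       diagram = diagram,
       structure = structure_res,
       files = out_files)
}
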