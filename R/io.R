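# ---------------------------------------------------------------------------
# On-disk artifacts: UTF-8 TSV tables (single header line, '.' decimal),
# YAML run configuration, multi-model PDB bead ensembles, JSON summaries.
# ---------------------------------------------------------------------------

.pose_columns <- c("sample_id", "tomogram_id", "array_id", "nuc_index",
                   "x", "y", "z", "nx", "ny", "nz",
                   "near_boundary", "linker_to_next_resolved")

.validate_pose_table <- function(df) {
  miss <- setdiff(.pose_columns, names(df))
  if (length(miss))
    stop("pose table format error: missing column(s) ",
         paste(miss, collapse = ", "))
  bad <- which(!is.finite(df$x) | !is.finite(df$y) | !is.finite(df$z))
  if (length(bad))
    stop("pose table validation error: non-finite centroid at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  nn <- sqrt(df$nx^2 + df$ny^2 + df$nz^2)
  bad <- which(abs(nn - 1) > 1e-6)
  if (length(bad))
    stop("pose table validation error: plane_normal not unit norm at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  for (aid in unique(df$array_id)) {
    ix <- sort(df$nuc_index[df$array_id == aid])
    if (anyDuplicated(ix) || !identical(ix, seq_along(ix)))
      stop("pose table validation error: nuc_index not unique/contiguous ",
           "in array ", aid)
  }
  invisible(df)
}

#' Read and write nucleosome pose tables
#'
#' UTF-8 TSV with a single header line; columns: sample_id, tomogram_id,
#' array_id, nuc_index (1-based, contiguous per array), x, y, z (centroid,
#' nm), nx, ny, nz (unit plane normal), near_boundary,
#' linker_to_next_resolved (logical). Invariants are validated on read and
#' write; violations name the offending rows.
#'
#' @param path file path.
#' @return `read_pose_table`: validated data.frame.
#' @export
read_pose_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  .validate_pose_table(df)
  df$near_boundary <- as.logical(df$near_boundary)
  df$linker_to_next_resolved <- as.logical(df$linker_to_next_resolved)
  df
}

#' @rdname read_pose_table
#' @param poses pose data.frame (e.g. `scene$poses`).
#' @export
write_pose_table <- function(poses, path) {
  .validate_pose_table(poses)
  utils::write.table(poses[, .pose_columns], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write traced-linker path tables
#'
#' TSV columns: array_id, linker_index (linker i joins nucleosomes i and
#' i+1), S_bp, E_bp (peel annotations, bp), resolved, points (polyline
#' serialized as `x,y,z;x,y,z;...` in nm; empty for unresolved linkers).
#'
#' @param path file path.
#' @return `read_path_table`: data.frame with a `points` list column of
#'   3-column matrices.
#' @export
read_path_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(points = "character"))
  need <- c("array_id", "linker_index", "S_bp", "E_bp", "resolved", "points")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("path table format error: missing column(s) ",
         paste(miss, collapse = ", "))
  if (any(df$S_bp < 0 | df$E_bp < 0))
    stop("path table validation error: negative peel values")
  pts <- lapply(df$points, function(s) {
    if (is.na(s) || !nzchar(s)) return(matrix(numeric(0), 0, 3))
    do.call(rbind, lapply(strsplit(s, ";", fixed = TRUE)[[1]],
                          function(p) as.numeric(strsplit(p, ",")[[1]])))
  })
  bad <- which(df$resolved & vapply(pts, nrow, 1L) < 2)
  if (length(bad))
    stop("path table validation error: resolved linker with < 2 points ",
         "at row(s) ", paste(utils::head(bad, 5), collapse = ", "))
  df$points <- pts
  df
}

#' @rdname read_path_table
#' @param paths path data.frame (e.g. `scene$paths`).
#' @export
write_path_table <- function(paths, path) {
  ser <- vapply(paths$points, function(m) {
    if (!nrow(m)) return("")
    paste(apply(m, 1, function(r)
      paste(format(r, digits = 15, trim = TRUE, scientific = FALSE),
            collapse = ",")), collapse = ";")
  }, character(1))
  out <- paths[, c("array_id", "linker_index", "S_bp", "E_bp", "resolved")]
  out$points <- ser
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write and read scenes (pose + path table pair)
#'
#' @param scene a `scene`.
#' @param prefix output path prefix: writes `<prefix>_poses.tsv` and
#'   `<prefix>_paths.tsv`.
#' @return `read_scene`: a `scene` (without generator truth).
#' @export
write_scene <- function(scene, prefix) {
  write_pose_table(scene$poses, paste0(prefix, "_poses.tsv"))
  write_path_table(scene$paths, paste0(prefix, "_paths.tsv"))
  invisible(prefix)
}

#' @rdname write_scene
#' @export
read_scene <- function(prefix) {
  structure(list(poses = read_pose_table(paste0(prefix, "_poses.tsv")),
                 paths = read_path_table(paste0(prefix, "_paths.tsv")),
                 truth = NULL),
            class = "scene")
}

# ---------------------------------------------------------------------------
# Multi-model PDB for bead ensembles
# ---------------------------------------------------------------------------

.pdb_bead_map <- data.frame(
  type = c("core_center", "core_charge", "anchor", "phantom", "lh",
           "tail_anchor", "tail", "linker"),
  name = c("CA", "CQ", "AN", "PH", "LH", "TA", "TL", "P"),
  res  = c("COR", "COR", "COR", "COR", "LHS", "TAI", "TAI", "DNA"),
  stringsAsFactors = FALSE)

#' Write an ensemble as a multi-model PDB file
#'
#' One MODEL block per configuration; pseudo-atoms typed by bead kind
#' (core, linker DNA, tail, linker histone) through atom/residue names;
#' coordinates in Angstrom (nm x 10). Phantom/anchor bookkeeping sites are
#' omitted by default.
#'
#' @param ensemble an `ensemble`.
#' @param path output path.
#' @param include_bookkeeping also write anchor/phantom sites.
#' @return the path, invisibly.
#' @export
write_ensemble_pdb <- function(ensemble, path, include_bookkeeping = FALSE) {
  stopifnot(inherits(ensemble, "ensemble"))
  if (!length(ensemble$frames)) stop("ensemble is empty")
  sites <- ensemble$sites
  keep <- if (include_bookkeeping) seq_len(nrow(sites)) else
    which(!sites$type %in% c("anchor", "phantom", "tail_anchor"))
  map <- .pdb_bead_map[match(sites$type[keep], .pdb_bead_map$type), ]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("REMARK   coarse-grained chromatin fiber ensemble (nm x 10)", con)
  for (mi in seq_along(ensemble$frames)) {
    writeLines(sprintf("MODEL     %4d", mi), con)
    xyz <- ensemble$frames[[mi]][keep, , drop = FALSE] * 10
    lines <- sprintf(
      "ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
      seq_along(keep) %% 100000, map$name, map$res,
      pmin(sites$core[keep] %% 10000, 9999),
      xyz[, 1], xyz[, 2], xyz[, 3])
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read back a multi-model PDB bead file
#'
#' @param path PDB path written by [write_ensemble_pdb()].
#' @return list with `frames` (list of n x 3 coordinate matrices, nm) and
#'   `atom_names` per site.
#' @export
read_ensemble_pdb <- function(path) {
  lines <- readLines(path)
  starts <- grep("^MODEL", lines)
  ends <- grep("^ENDMDL", lines)
  stopifnot(length(starts) == length(ends))
  frames <- vector("list", length(starts))
  nm <- NULL
  for (i in seq_along(starts)) {
    at <- lines[(starts[i] + 1):(ends[i] - 1)]
    at <- at[startsWith(at, "ATOM")]
    xyz <- cbind(as.numeric(substr(at, 31, 38)),
                 as.numeric(substr(at, 39, 46)),
                 as.numeric(substr(at, 47, 54))) / 10
    frames[[i]] <- xyz
    if (is.null(nm)) nm <- trimws(substr(at, 13, 16))
  }
  list(frames = frames, atom_names = nm)
}

# ---------------------------------------------------------------------------
# Run configuration (YAML)
# ---------------------------------------------------------------------------

.config_defaults <- function() {
  list(seed = NULL,
       samples = c("PN1", "PN56"),
       simulator = list(NaCl_mM = 150, mg = FALSE, lh_per_nucleosome = 1,
                        replicates = 20, ensemble_size = 2000,
                        n_nucleosomes = 23, burnin_sweeps = 2000,
                        sweep_interval = 10,
                        amps = c(0.35, 0.6, 0.15, 0.12, 0.4)),
       thresholds = list(contact_nm = 11, trans_nm = 28, boundary_nm = 5,
                         stack_para_deg = 25, stack_N_nm = 8, stem_nm = 2.5))
}

#' Load a run configuration
#'
#' YAML with keys `seed`, `samples`, `simulator`, `thresholds` (see the
#' documented defaults in the methods vignette). Missing keys take
#' defaults; unknown keys raise an error listing the valid ones; a missing
#' seed is auto-generated with a warning and logged. The effective
#' configuration is echoed to the log.
#'
#' @param path YAML file path, or `NULL` for all defaults.
#' @return list of class `run_config`.
#' @export
load_config <- function(path = NULL) {
  cfg <- .config_defaults()
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  merge_level <- function(base, upd, ctx) {
    bad <- setdiff(names(upd), names(base))
    if (length(bad))
      stop(sprintf("unknown config key(s) %s in %s; valid keys: %s",
                   paste(bad, collapse = ", "), ctx,
                   paste(names(base), collapse = ", ")))
    for (k in names(upd)) {
      base[[k]] <- if (is.list(base[[k]]) && is.list(upd[[k]]))
        merge_level(base[[k]], upd[[k]], paste0(ctx, "$", k)) else upd[[k]]
    }
    base
  }
  cfg <- merge_level(cfg, user, "config")
  if (is.null(cfg$seed)) {
    cfg$seed <- as.integer(Sys.time()) %% 1000000L
    warning("no seed in config; auto-generated seed ", cfg$seed)
  }
  stopifnot(cfg$simulator$ensemble_size >= 1)
  th <- unlist(cfg$thresholds)
  if (any(th <= 0)) stop("all thresholds must be > 0")
  class(cfg) <- "run_config"
  nuc_log("effective config (hash %s): seed=%d",
          substr(config_hash(cfg), 1, 8), cfg$seed)
  cfg
}

#' Short content hash of a configuration
#' @param cfg a `run_config`.
#' @return character hash.
#' @export
config_hash <- function(cfg) {
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  # tiny polynomial rolling hash; enough to fingerprint a config in logs
  h <- 0
  for (b in utf8ToInt(as.character(s))) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Package log messages
#'
#' Messages go to stderr via [message()] and honor
#' `options(nucarray.log_level =)` with levels "quiet" < "info" (default)
#' < "debug".
#'
#' @param fmt sprintf format.
#' @param ... format arguments.
#' @param level message level.
#' @export
nuc_log <- function(fmt, ..., level = "info") {
  opt <- getOption("nucarray.log_level", "info")
  rank <- c(quiet = 0, info = 1, debug = 2)
  if (rank[[opt]] >= rank[[level]])
    message(sprintf("[nucarray] %s", sprintf(fmt, ...)))
  invisible(NULL)
}
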