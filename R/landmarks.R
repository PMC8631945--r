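#' Landmark configuration of a single mandible
#'
#' Bundles the ordered, labelled landmark coordinates of one specimen
#' together with its side and the semantic roles of individual points.
#' Coordinates may be 2D (compression fossils) or 3D (extant material);
#' units are arbitrary (pixels or mm) because every downstream statistic
#' is size-independent.
#'
#' @param specimen_id Character scalar identifying the specimen.
#' @param points Numeric matrix, one row per landmark, 2 or 3 columns.
#'   Row names are the landmark labels; unlabelled input is labelled
#'   `p1..pk`.
#' @param side `"left"`, `"right"`, or `NA` when unknown.
#' @param roles Named character vector mapping landmark labels to roles
#'   among `"condyle_anterior"`, `"condyle_posterior"`,
#'   `"adductor_attachment"`, `"edge_point"`. May cover only a subset of
#'   the landmarks.
#'
#' @return An object of class `landmark_config`.
#' @export
landmark_config <- function(specimen_id, points, side = NA_character_,
                            roles = NULL) {
  stopifnot(is.character(specimen_id), length(specimen_id) == 1L)
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) < 2L || ncol(points) > 3L)
    stop("points must have 2 or 3 columns, got ", ncol(points))
  if (nrow(points) < 3L)
    stop("configuration '", specimen_id, "' needs at least 3 landmarks")
  if (!all(is.finite(points)))
    stop("configuration '", specimen_id, "' contains non-finite coordinates")
  if (is.null(rownames(points)))
    rownames(points) <- paste0("p", seq_len(nrow(points)))
  if (anyDuplicated(rownames(points)))
    stop("duplicate landmark labels in configuration '", specimen_id, "'")
  if (!is.na(side) && !side %in% c("left", "right"))
    stop("side must be 'left', 'right' or NA")
  if (!is.null(roles)) {
    roles <- unlist(roles)
    bad <- setdiff(names(roles), rownames(points))
    if (length(bad))
      stop("roles refer to unknown landmarks: ", paste(bad, collapse = ", "))
    ok <- c("condyle_anterior", "condyle_posterior",
            "adductor_attachment", "edge_point")
    if (!all(roles %in% ok))
      stop("unknown role(s): ", paste(setdiff(roles, ok), collapse = ", "))
  }
  structure(
    list(specimen_id = specimen_id, points = points,
         side = side, roles = roles),
    class = "landmark_config")
}

#' @export
print.landmark_config <- function(x, ...) {
  cat("landmark_config '", x$specimen_id, "': ",
      nrow(x$points), " landmarks, ", ncol(x$points), "D",
      if (!is.na(x$side)) paste0(", side ", x$side),
      if (length(x$roles)) paste0(", ", sum(x$roles == "edge_point"),
                                  " edge points"),
      "\n", sep = "")
  invisible(x)
}

#' Number of landmarks and dimensionality helpers
#' @param config A [landmark_config].
#' @return Integer scalar.
#' @keywords internal
config_dim <- function(config) ncol(config$points)

#' Read landmark configurations from a TPS file
#'
#' Supports the common TPS dialect: `LM=` records hold 2D coordinates,
#' `LM3=` records 3D coordinates; optional `ID=`, `IMAGE=` and `SCALE=`
#' keys. `SCALE` multiplies the coordinates of its record. Unknown keys
#' are ignored with a warning. Landmarks are labelled `p1..pk` in file
#' order.
#'
#' @param path Path to a TPS file.
#' @return A list of [landmark_config] objects, in file order.
#' @export
read_tps <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  configs <- list()
  i <- 1L
  rec <- 0L
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "") { i <- i + 1L; next }
    m <- regmatches(ln, regexec("^(LM3?)\\s*=\\s*(\\S+)$", ln))[[1]]
    if (length(m) == 0L)
      stop("TPS parse error at line ", i,
           ": expected an LM= or LM3= count line, got '", ln, "'")
    d <- if (m[2] == "LM3") 3L else 2L
    k <- suppressWarnings(as.integer(m[3]))
    if (is.na(k) || k < 0L)
      stop("TPS parse error at line ", i, ": malformed count '", m[3], "'")
    rec <- rec + 1L
    i <- i + 1L
    coords <- matrix(NA_real_, k, d)
    for (j in seq_len(k)) {
      if (i > length(lines))
        stop("TPS parse error: record ", rec, " declares ", k,
             " landmarks but the file ends after ", j - 1L)
      vals <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]),
                                                   "\\s+")[[1]]))
      if (length(vals) != d || anyNA(vals))
        stop("TPS parse error at line ", i, ": record ", rec,
             " declares ", k, " landmarks of dimension ", d,
             " but row ", j, " is '", trimws(lines[i]), "'")
      coords[j, ] <- vals
      i <- i + 1L
    }
    id <- paste0("tps_", rec)
    scale <- NULL
    while (i <= length(lines) &&
           grepl("^[A-Za-z]+\\s*=", trimws(lines[i])) &&
           !grepl("^LM3?\\s*=", trimws(lines[i]))) {
      kv <- trimws(lines[i])
      key <- toupper(sub("\\s*=.*$", "", kv))
      val <- trimws(sub("^[A-Za-z]+\\s*=", "", kv))
      if (key == "ID") id <- val
      else if (key == "SCALE") {
        scale <- suppressWarnings(as.numeric(val))
        if (is.na(scale))
          stop("TPS parse error at line ", i, ": bad SCALE '", val, "'")
      } else if (key != "IMAGE")
        warning("ignoring unknown TPS key '", key, "' at line ", i)
      i <- i + 1L
    }
    if (!is.null(scale)) coords <- coords * scale
    configs[[rec]] <- landmark_config(id, coords)
  }
  configs
}

#' Write landmark configurations to a TPS file
#'
#' @param configs A list of [landmark_config] objects (all the same
#'   dimension).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tps <- function(configs, path) {
  if (inherits(configs, "landmark_config")) configs <- list(configs)
  out <- character(0)
  for (cfg in configs) {
    d <- config_dim(cfg)
    hdr <- if (d == 3L) "LM3=" else "LM="
    out <- c(out, paste0(hdr, nrow(cfg$points)),
             apply(cfg$points, 1, paste, collapse = " "),
             paste0("ID=", cfg$specimen_id))
  }
  writeLines(out, path)
  invisible(path)
}

#' Read landmark configurations from a long-format CSV
#'
#' Expected columns: `specimen_id`, `label`, `x`, `y`, optionally `z`,
#' `role`, `side`. Rows are grouped by specimen in file order.
#'
#' @param path Path to a CSV file.
#' @return A list of [landmark_config] objects.
#' @export
read_landmarks_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen_id", "label", "x", "y")
  if (!all(need %in% names(df)))
    stop("landmark CSV must contain columns: ", paste(need, collapse = ", "))
  has_z <- "z" %in% names(df) && !all(is.na(df$z))
  ids <- unique(df$specimen_id)
  lapply(ids, function(id) {
    sub <- df[df$specimen_id == id, , drop = FALSE]
    pts <- as.matrix(sub[, c("x", "y", if (has_z) "z")])
    dimnames(pts) <- list(sub$label, NULL)
    roles <- NULL
    if ("role" %in% names(sub)) {
      keep <- !is.na(sub$role) & sub$role != ""
      if (any(keep)) roles <- stats::setNames(sub$role[keep], sub$label[keep])
    }
    side <- NA_character_
    if ("side" %in% names(sub)) {
      s <- unique(sub$side[!is.na(sub$side) & sub$side != ""])
      if (length(s) == 1L) side <- s
    }
    landmark_config(id, pts, side = side, roles = roles)
  })
}

#' Write landmark configurations to a long-format CSV
#' @param configs List of [landmark_config] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_landmarks_csv <- function(configs, path) {
  if (inherits(configs, "landmark_config")) configs <- list(configs)
  rows <- lapply(configs, function(cfg) {
    d <- config_dim(cfg)
    labs <- rownames(cfg$points)
    data.frame(
      specimen_id = cfg$specimen_id,
      label = labs,
      x = cfg$points[, 1], y = cfg$points[, 2],
      z = if (d == 3L) cfg$points[, 3] else NA_real_,
      role = if (length(cfg$roles))
        ifelse(labs %in% names(cfg$roles), cfg$roles[labs], "") else "",
      side = ifelse(is.na(cfg$side), "", cfg$side),
      stringsAsFactors = FALSE, row.names = NULL)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Mirror a configuration onto a reference side
#'
#' Left and right mandibles must be co-orientable before joint
#' alignment; this negates the first coordinate axis when the
#' configuration's side differs from the reference and relabels the
#' side. Applying the operation twice returns the original.
#'
#' @param config A [landmark_config] with known side.
#' @param reference_side `"left"` or `"right"`.
#' @return A [landmark_config] on the reference side.
#' @export
reflect_to_reference <- function(config, reference_side = "right") {
  stopifnot(inherits(config, "landmark_config"))
  if (!reference_side %in% c("left", "right"))
    stop("reference_side must be 'left' or 'right'")
  if (is.na(config$side))
    stop("configuration '", config$specimen_id, "' has unknown side")
  if (config$side == reference_side) return(config)
  pts <- config$points
  pts[, 1] <- -pts[, 1]
  landmark_config(config$specimen_id, pts, side = reference_side,
                  roles = config$roles)
}
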