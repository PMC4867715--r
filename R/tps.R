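#' Read landmark configurations from a TPS file
#'
#' Parses the plain-text TPS dialect produced by common 2D digitizing tools:
#' each record starts with `LM=<k>`, followed by `k` whitespace-separated
#' coordinate lines, then optional `ID=`, `IMAGE=` and `SCALE=` lines.
#' Outline/curve blocks are not supported and raise an error. If a record
#' has no `SCALE=` line its scale defaults to 1 with a warning.
#'
#' @param path TPS file path.
#' @param tooth `"M1"` or `"M2"`, applied to every record.
#' @param side `"right"` or `"left"`, applied to every record (the TPS
#'   format carries no side field).
#' @param flip_y if `TRUE`, negate the y coordinates on input (image-origin
#'   conventions differ between digitizers; y is made to increase lingually
#'   / "up"). The configurations are shifted back into the positive
#'   quadrant.
#' @param fossil logical flag applied to every record.
#' @param n_landmarks expected landmark count per record.
#' @return A list of [landmark_config()] objects, in file order.
#' @seealso [write_tps()], [read_landmark_csv()]
#' @export
read_tps <- function(path, tooth = c("M1", "M2"), side = c("right", "left"),
                     flip_y = FALSE, fossil = FALSE, n_landmarks = 15L) {
  tooth <- match.arg(tooth)
  side <- match.arg(side)
  if (!file.exists(path)) stop("TPS file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty TPS file: ", path)
  starts <- grep("^LM\\s*=", lines, ignore.case = TRUE)
  if (!length(starts) || starts[1] != 1L)
    stop("malformed TPS file (must start with LM=): ", path)
  ends <- c(starts[-1] - 1L, length(lines))
  configs <- vector("list", length(starts))
  for (r in seq_along(starts)) {
    block <- lines[starts[r]:ends[r]]
    k <- suppressWarnings(as.integer(sub("^LM\\s*=\\s*", "", block[1],
                                         ignore.case = TRUE)))
    if (is.na(k) || k != n_landmarks)
      stop(sprintf("record %d: LM=%s, expected %d landmarks", r,
                   sub("^LM\\s*=\\s*", "", block[1]), n_landmarks))
    if (any(grepl("^(CURVES|POINTS|OUTLINES)\\s*=", block,
                  ignore.case = TRUE)))
      stop(sprintf("record %d: curve/outline blocks are not supported", r))
    body <- block[-1]
    is_kv <- grepl("^[A-Za-z]+\\s*=", body)
    coord_lines <- body[!is_kv]
    if (length(coord_lines) != k)
      stop(sprintf("record %d: found %d coordinate lines, expected %d",
                   r, length(coord_lines), k))
    coords <- t(vapply(seq_along(coord_lines), function(i) {
      parts <- suppressWarnings(as.numeric(strsplit(coord_lines[i],
                                                    "\\s+")[[1]]))
      if (length(parts) != 2L || anyNA(parts))
        stop(sprintf("record %d, landmark line %d: non-numeric or not 2D: '%s'",
                     r, i, coord_lines[i]))
      parts
    }, numeric(2)))
    kv <- body[is_kv]
    get_kv <- function(key) {
      hit <- grep(paste0("^", key, "\\s*="), kv, ignore.case = TRUE,
                  value = TRUE)
      if (!length(hit)) return(NULL)
      sub(paste0("^", key, "\\s*=\\s*"), "", hit[1], ignore.case = TRUE)
    }
    id <- get_kv("ID") %||% sprintf("record_%d", r)
    image <- get_kv("IMAGE") %||% ""
    scale_chr <- get_kv("SCALE")
    if (is.null(scale_chr)) {
      warning(sprintf("record %d ('%s'): no SCALE= line, assuming scale 1",
                      r, id), call. = FALSE)
      scale <- 1
    } else {
      scale <- suppressWarnings(as.numeric(scale_chr))
      if (is.na(scale))
        stop(sprintf("record %d: non-numeric SCALE= '%s'", r, scale_chr))
    }
    if (flip_y) {
      coords[, 2] <- -coords[, 2]
      coords <- sweep(coords, 2L, apply(coords, 2L, min))
    }
    configs[[r]] <- landmark_config(coords, id = id, tooth = tooth,
                                    side = side, scale = scale,
                                    source = image, fossil = fossil,
                                    n_landmarks = n_landmarks)
  }
  configs
}

#' Write landmark configurations to a TPS file
#'
#' Inverse of [read_tps()]: emits `LM=`, coordinate lines, `ID=`, `IMAGE=`
#' (if non-empty) and `SCALE=` for each configuration.
#'
#' @param configs list of [landmark_config()] objects.
#' @param path output file path.
#' @param digits significant digits for coordinates.
#' @return `path`, invisibly.
#' @export
write_tps <- function(configs, path, digits = 12) {
  if (inherits(configs, "landmark_config")) configs <- list(configs)
  out <- unlist(lapply(configs, function(cf) {
    c(sprintf("LM=%d", nrow(cf$landmarks)),
      apply(cf$landmarks, 1L, function(p)
        paste(format(p, digits = digits, trim = TRUE, scientific = FALSE),
              collapse = " ")),
      sprintf("ID=%s", cf$id),
      if (nzchar(cf$source)) sprintf("IMAGE=%s", cf$source),
      sprintf("SCALE=%s", format(cf$scale, digits = digits, trim = TRUE,
                                 scientific = FALSE)))
  }))
  writeLines(out, path)
  invisible(path)
}

#' Read landmark configurations from a coordinate-table CSV
#'
#' Expects columns `specimen_id`, `tooth`, `side`, `scale`, then
#' `x1,y1,...,x15,y15`; an optional logical `fossil` column flags unknowns.
#'
#' @param path CSV file path.
#' @param n_landmarks expected landmark count.
#' @return A list of [landmark_config()] objects.
#' @export
read_landmark_csv <- function(path, n_landmarks = 15L) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen_id", "tooth", "side", "scale",
            paste0(rep(c("x", "y"), n_landmarks),
                   rep(seq_len(n_landmarks), each = 2L)))
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("landmark CSV lacks columns: ", paste(miss, collapse = ", "))
  if (is.null(df$fossil)) df$fossil <- FALSE
  lapply(seq_len(nrow(df)), function(i) {
    coords <- matrix(as.numeric(df[i, need[-(1:4)]]), ncol = 2L,
                     byrow = TRUE)
    landmark_config(coords, id = df$specimen_id[i], tooth = df$tooth[i],
                    side = df$side[i], scale = df$scale[i],
                    fossil = isTRUE(as.logical(df$fossil[i])),
                    n_landmarks = n_landmarks)
  })
}

#' Write landmark configurations to a coordinate-table CSV
#'
#' @param configs list of [landmark_config()] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_landmark_csv <- function(configs, path) {
  if (inherits(configs, "landmark_config")) configs <- list(configs)
  k <- nrow(configs[[1]]$landmarks)
  rows <- lapply(configs, function(cf) {
    v <- flatten_shape(cf$landmarks)
    row <- data.frame(specimen_id = cf$id, tooth = cf$tooth, side = cf$side,
                      scale = cf$scale, fossil = cf$fossil,
                      stringsAsFactors = FALSE)
    coords <- as.data.frame(as.list(v))
    names(coords) <- paste0(rep(c("x", "y"), k), rep(seq_len(k), each = 2L))
    cbind(row, coords)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read a taxonomy table
#'
#' Reads and validates the specimen taxonomy CSV with columns
#' `specimen_id`, `species`, `genus`, `subfamily_G` (eight-subfamily
#' scheme), `subfamily_R` (five-subfamily scheme), `family`, and optional
#' `fossil_flag`, `fossil_code`. Subfamily and family labels are checked
#' against the two platyrrhine classification schemes.
#'
#' @param path CSV file path.
#' @return A validated taxonomy data frame.
#' @seealso [platyrrhine_taxonomy()] for the built-in genus-level mapping.
#' @export
read_taxonomy <- function(path) {
  validate_taxonomy(utils::read.csv(path, stringsAsFactors = FALSE))
}
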