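#' The 15-landmark lower-molar scheme
#'
#' Definitions of the 15 occlusal landmarks digitized on every molar: the
#' tips of the four main cusps (entoconid, metaconid, protoconid, hypoconid)
#' forming the occlusal polygon, eight points along the crown outline
#' (groove intersections, maximum-curvature points below each cusp, and the
#' most mesial and most distal points of the mid mesiodistal line), and
#' three points on the crests. Types follow the usual landmark typology:
#' type 2 points are geometric extrema (cusp tips, maximum curvature),
#' type 3 points are constructed relative to other features.
#'
#' @return A data frame with columns `index`, `type` (`"type2"`/`"type3"`)
#'   and `definition`.
#' @export
#' @examples
#' molar_landmarks()
molar_landmarks <- function() {
  data.frame(
    index = 1:15,
    type = c("type2", "type2", "type2", "type2", "type3", "type2", "type3",
             "type2", "type3", "type2", "type3", "type2", "type2", "type2",
             "type2"),
    definition = c(
      "Tip of the distolingual cusp (entoconid)",
      "Tip of the mesiolingual cusp (metaconid)",
      "Tip of the mesiobuccal cusp (protoconid)",
      "Tip of the distobuccal cusp (hypoconid)",
      "Most distal point of the mid mesiodistal line on the crown outline",
      "Point of maximum curvature directly below the entoconid",
      "Point on the dental crown outline at the lingual groove",
      "Point of maximum curvature directly below the metaconid",
      "Most mesial point of the mid mesiodistal line on the crown outline",
      "Point of maximum curvature directly below the protoconid",
      "Point on the dental crown outline at the buccal (mesial) groove",
      "Point of maximum curvature directly below the hypoconid",
      "Midpoint between the preentocristid and postmetacristid",
      "Lowest point on the protocristid",
      "Lowest point on the crista obliqua"
    ),
    stringsAsFactors = FALSE
  )
}

#' Landmark index remap under left/right mirroring
#'
#' When a left molar is reflected onto right-side orientation the buccal and
#' lingual sides exchange, so buccal landmarks must be relabelled as their
#' lingual homologues and vice versa: entoconid and hypoconid swap (1, 4),
#' metaconid and protoconid swap (2, 3), and the outline points below them
#' swap pairwise (6, 12), (7, 11), (8, 10). The midline and crest points
#' (5, 9, 13, 14, 15) keep their indices. The remap is an involution.
#'
#' @return An integer permutation of `1:15`; entry `i` gives the landmark of
#'   the mirrored configuration that takes index `i` in the standardized one.
#' @export
#' @examples
#' p <- mirror_pairs()
#' stopifnot(identical(p[p], 1:15))
mirror_pairs <- function() {
  c(4L, 3L, 2L, 1L, 5L, 12L, 11L, 10L, 9L, 8L, 7L, 6L, 13L, 14L, 15L)
}

#' Construct a single landmark configuration
#'
#' Bundles one specimen's digitized landmarks with its identifying metadata
#' and validates the configuration: exactly `n_landmarks` finite points, no
#' two landmarks exactly coincident, strictly positive scale.
#'
#' @param landmarks a 15 x 2 numeric matrix of (x, y) image coordinates.
#' @param id specimen identifier (unique within a tooth).
#' @param tooth `"M1"` or `"M2"`.
#' @param side `"left"` or `"right"`.
#' @param scale millimetres per image unit; multiplied in by [apply_scale()].
#' @param source free-text provenance (collection, figure).
#' @param fossil logical; `TRUE` for fossil (unclassified) specimens.
#' @param n_landmarks expected landmark count.
#' @return An object of class `"landmark_config"`.
#' @export
landmark_config <- function(landmarks, id, tooth = c("M1", "M2"),
                            side = c("right", "left"), scale = 1,
                            source = "", fossil = FALSE, n_landmarks = 15L) {
  tooth <- match.arg(tooth)
  side <- match.arg(side)
  landmarks <- as_shape_matrix(landmarks, "landmarks")
  if (nrow(landmarks) != n_landmarks)
    stop(sprintf("configuration '%s' has %d landmarks, expected %d",
                 id, nrow(landmarks), n_landmarks), call. = FALSE)
  if (anyDuplicated(landmarks) > 0L)
    stop(sprintf("configuration '%s' has exactly coincident landmarks", id),
         call. = FALSE)
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) ||
      scale <= 0)
    stop(sprintf("configuration '%s': scale must be a positive number", id),
         call. = FALSE)
  structure(
    list(landmarks = landmarks, id = as.character(id), tooth = tooth,
         side = side, scale = as.numeric(scale), source = as.character(source),
         fossil = isTRUE(fossil)),
    class = "landmark_config"
  )
}

#' @export
print.landmark_config <- function(x, ...) {
  cat(sprintf("Landmark configuration '%s' (%s, %s side, scale %g mm/unit%s)\n",
              x$id, x$tooth, x$side, x$scale,
              if (x$fossil) ", fossil" else ""))
  cat(sprintf("  %d landmarks, centroid size %.4f\n",
              nrow(x$landmarks), centroid_size(x$landmarks)))
  invisible(x)
}

#' Standardize a configuration to right-side orientation
#'
#' Left-side configurations are reflected across the horizontal
#' (mesiodistal) axis, which exchanges the buccal and lingual sides while
#' keeping the mesial border facing the same direction, and the landmark
#' indices are remapped so that each index keeps its anatomical meaning
#' (see [mirror_pairs()]). The reflected configuration is translated back
#' into the positive quadrant. Right-side configurations are returned
#' unchanged. Applying the function twice is a no-op because the output is
#' always flagged as right-sided.
#'
#' @param config a [landmark_config()].
#' @param remap integer permutation applied after mirroring; defaults to
#'   [mirror_pairs()]. Use `seq_len(nrow(...))` to disable remapping (e.g.
#'   when landmarks were digitized by anatomical definition rather than by
#'   screen position).
#' @return A right-sided `landmark_config`.
#' @export
standardize_side <- function(config, remap = mirror_pairs()) {
  stopifnot(inherits(config, "landmark_config"))
  if (config$side == "right") return(config)
  lm <- config$landmarks
  lm[, 2] <- -lm[, 2]
  lm <- lm[remap, , drop = FALSE]
  # re-center into the positive quadrant (GPA later removes translation)
  lm <- sweep(lm, 2L, apply(lm, 2L, min))
  config$landmarks <- lm
  config$side <- "right"
  config
}

#' Apply the millimetre scale factor
#'
#' Multiplies the coordinates by `scale` (mm per image unit) and resets the
#' scale to 1, so coordinates are afterwards in millimetres. A second call
#' is a no-op.
#'
#' @param config a [landmark_config()].
#' @return The rescaled `landmark_config` with `scale = 1`.
#' @export
apply_scale <- function(config) {
  stopifnot(inherits(config, "landmark_config"))
  if (config$scale <= 0) stop("scale must be strictly positive")
  config$landmarks <- config$landmarks * config$scale
  config$scale <- 1
  config
}

#' Assemble a validated shape dataset
#'
#' Combines landmark configurations for one tooth with a taxonomy table.
#' All configurations must share the tooth, carry unique specimen ids, and
#' every extant (non-fossil) specimen must appear in the taxonomy. Fossil
#' configurations may lack taxonomy rows; they are flagged and excluded from
#' extant-only operations downstream.
#'
#' @param configs list of [landmark_config()] objects.
#' @param taxonomy data frame with columns `specimen_id`, `species`,
#'   `genus`, `subfamily_G`, `subfamily_R`, `family`, and optionally
#'   `fossil_flag`, `fossil_code` (see [read_taxonomy()]).
#' @param tooth `"M1"` or `"M2"`; defaults to the tooth of the
#'   configurations.
#' @return An object of class `"shape_dataset"`: list with `configs`,
#'   `info` (per-specimen data frame), `taxonomy`, `tooth`.
#' @export
shape_dataset <- function(configs, taxonomy, tooth = NULL) {
  if (!length(configs)) stop("no configurations supplied")
  if (!all(vapply(configs, inherits, logical(1), "landmark_config")))
    stop("'configs' must be a list of landmark_config objects")
  teeth <- unique(vapply(configs, `[[`, character(1), "tooth"))
  if (length(teeth) > 1L)
    stop("mixed teeth in one dataset: ", paste(teeth, collapse = ", "))
  tooth <- tooth %||% teeth
  if (!identical(tooth, teeth))
    stop(sprintf("configurations are %s but tooth = %s requested",
                 teeth, tooth))
  ids <- vapply(configs, `[[`, character(1), "id")
  if (anyDuplicated(ids))
    stop("duplicate specimen ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(configs) <- ids
  taxonomy <- validate_taxonomy(taxonomy)
  fossil <- vapply(configs, `[[`, logical(1), "fossil")
  tax_fossil <- ids %in% taxonomy$specimen_id[taxonomy$fossil_flag]
  fossil <- fossil | tax_fossil
  missing <- setdiff(ids[!fossil], taxonomy$specimen_id)
  if (length(missing))
    stop("extant specimens missing from taxonomy: ",
         paste(missing, collapse = ", "))
  info <- data.frame(
    specimen_id = ids,
    side = vapply(configs, `[[`, character(1), "side"),
    scale = vapply(configs, `[[`, numeric(1), "scale"),
    fossil = fossil,
    stringsAsFactors = FALSE, row.names = NULL
  )
  m <- match(ids, taxonomy$specimen_id)
  for (col in c("species", "genus", "subfamily_G", "subfamily_R", "family"))
    info[[col]] <- taxonomy[[col]][m]
  structure(list(configs = configs, info = info, taxonomy = taxonomy,
                 tooth = tooth),
            class = "shape_dataset")
}

#' @export
print.shape_dataset <- function(x, ...) {
  nf <- sum(x$info$fossil)
  cat(sprintf("Shape dataset: %d %s configurations (%d extant, %d fossil)\n",
              nrow(x$info), x$tooth, nrow(x$info) - nf, nf))
  ext <- x$info[!x$info$fossil, ]
  if (nrow(ext))
    cat(sprintf("  %d species, %d genera, %d subfamilies (G), %d families\n",
                length(unique(ext$species)), length(unique(ext$genus)),
                length(unique(ext$subfamily_G)),
                length(unique(ext$family))))
  invisible(x)
}

# Landmark coordinate matrices of a dataset as a named list.
dataset_shapes <- function(dataset) {
  lapply(dataset$configs, `[[`, "landmarks")
}

valid_subfamilies_G <- c("Cebinae", "Saimiriinae", "Callitrichinae",
                         "Pitheciinae", "Callicebinae", "Aotinae",
                         "Atelinae", "Alouattinae")
valid_subfamilies_R <- c("Cebinae", "Callitrichinae", "Pitheciinae",
                         "Homunculinae", "Atelinae")
valid_families <- c("Cebidae", "Atelidae", "Pitheciidae")

validate_taxonomy <- function(taxonomy) {
  taxonomy <- as.data.frame(taxonomy, stringsAsFactors = FALSE)
  need <- c("specimen_id", "species", "genus", "subfamily_G", "subfamily_R",
            "family")
  miss <- setdiff(need, names(taxonomy))
  if (length(miss))
    stop("taxonomy lacks columns: ", paste(miss, collapse = ", "))
  if (is.null(taxonomy$fossil_flag)) taxonomy$fossil_flag <- FALSE
  taxonomy$fossil_flag <- as.logical(taxonomy$fossil_flag)
  if (is.null(taxonomy$fossil_code)) taxonomy$fossil_code <- NA_character_
  if (anyDuplicated(taxonomy$specimen_id))
    stop("duplicate specimen ids in taxonomy")
  ext <- taxonomy[!taxonomy$fossil_flag, ]
  for (col in c("species", "genus", "subfamily_G", "subfamily_R", "family"))
    if (any(is.na(ext[[col]]) | ext[[col]] == ""))
      stop(sprintf("extant specimens with missing %s in taxonomy", col))
  bad <- setdiff(unique(ext$subfamily_G), valid_subfamilies_G)
  if (length(bad))
    stop("unknown subfamily_G labels: ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(ext$subfamily_R), valid_subfamilies_R)
  if (length(bad))
    stop("unknown subfamily_R labels: ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(ext$family), valid_families)
  if (length(bad))
    stop("unknown family labels: ", paste(bad, collapse = ", "))
  taxonomy
}
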