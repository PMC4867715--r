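#' Idealized lower-molar landmark template
#'
#' A deterministic 15-landmark configuration honoring the occlusal
#' topology of a right lower molar (mesial to +x, lingual to +y): the four
#' cusp tips form the occlusal polygon inside a simple (non-crossing)
#' eight-point crown outline, with three interior crest points. Scaled to
#' unit centroid size.
#'
#' @return A 15 x 2 matrix.
#' @export
molar_template <- function() {
  lm <- rbind(
    c(-0.45,  0.45),   # 1 entoconid (distolingual cusp)
    c( 0.45,  0.45),   # 2 metaconid (mesiolingual cusp)
    c( 0.45, -0.45),   # 3 protoconid (mesiobuccal cusp)
    c(-0.45, -0.45),   # 4 hypoconid (distobuccal cusp)
    c(-1.00,  0.00),   # 5 most distal outline point
    c(-0.55,  0.85),   # 6 outline below entoconid
    c( 0.00,  0.95),   # 7 lingual groove
    c( 0.55,  0.85),   # 8 outline below metaconid
    c( 1.00,  0.00),   # 9 most mesial outline point
    c( 0.55, -0.85),   # 10 outline below protoconid
    c( 0.00, -0.95),   # 11 buccal groove
    c(-0.55, -0.85),   # 12 outline below hypoconid
    c( 0.00,  0.50),   # 13 preentocristid/postmetacristid midpoint
    c( 0.45,  0.00),   # 14 lowest point of the protocristid
    c(-0.30, -0.10)    # 15 lowest point of the crista obliqua
  )
  colnames(lm) <- c("x", "y")
  preshape(lm) + 0  # centered, unit centroid size
}

#' Built-in platyrrhine taxonomy with study sample sizes
#'
#' The extant comparative sample structure used as the generator default:
#' 18 genera in 3 families, with both subfamily schemes (the
#' eight-subfamily arrangement `subfamily_G` and the five-subfamily
#' arrangement `subfamily_R`, which sinks Saimiri into Cebinae and unites
#' Aotus and Callicebus in Homunculinae), and per-species specimen counts.
#'
#' @return A data frame with columns `species`, `genus`, `subfamily_G`,
#'   `subfamily_R`, `family`, `n`.
#' @export
platyrrhine_taxonomy <- function() {
  gmap <- data.frame(
    genus = c("Cebus", "Sapajus", "Saimiri", "Callithrix", "Mico",
              "Cebuella", "Callimico", "Leontopithecus", "Saguinus",
              "Aotus", "Callicebus", "Cacajao", "Chiropotes", "Pithecia",
              "Lagothrix", "Brachyteles", "Ateles", "Alouatta"),
    subfamily_G = c("Cebinae", "Cebinae", "Saimiriinae", "Callitrichinae",
                    "Callitrichinae", "Callitrichinae", "Callitrichinae",
                    "Callitrichinae", "Callitrichinae", "Aotinae",
                    "Callicebinae", "Pitheciinae", "Pitheciinae",
                    "Pitheciinae", "Atelinae", "Atelinae", "Atelinae",
                    "Alouattinae"),
    subfamily_R = c("Cebinae", "Cebinae", "Cebinae", "Callitrichinae",
                    "Callitrichinae", "Callitrichinae", "Callitrichinae",
                    "Callitrichinae", "Callitrichinae", "Homunculinae",
                    "Homunculinae", "Pitheciinae", "Pitheciinae",
                    "Pitheciinae", "Atelinae", "Atelinae", "Atelinae",
                    "Atelinae"),
    family = c("Cebidae", "Cebidae", "Cebidae", "Cebidae", "Cebidae",
               "Cebidae", "Cebidae", "Cebidae", "Cebidae", "Cebidae",
               "Pitheciidae", "Pitheciidae", "Pitheciidae", "Pitheciidae",
               "Atelidae", "Atelidae", "Atelidae", "Atelidae"),
    stringsAsFactors = FALSE
  )
  sp <- list(
    Cebus = c(albifrons = 9, olivaceus = 6),
    Sapajus = c(apella = 14, libidinosus = 15, nigritus = 15, robustus = 15,
                xanthosternos = 7),
    Saimiri = c(boliviensis = 17, sciureus = 25, ustus = 18, vanzolinii = 8),
    Callithrix = c(aurita = 11, geoffroyi = 15, jacchus = 21, kuhlii = 20,
                   penicillata = 14),
    Mico = c(argentata = 21, chrysoleuca = 16, emiliae = 6,
             humeralifer = 16, melanurus = 8),
    Cebuella = c(pygmaea = 7),
    Callimico = c(goeldii = 4),
    Leontopithecus = c(chrysomelas = 5, rosalia = 17),
    Saguinus = c(fuscicollis = 13, imperator = 10, labiatus = 9, midas = 22,
                 mystax = 13, niger = 14),
    Aotus = c(azarae = 4, nigriceps = 9, trivirgatus = 21),
    Callicebus = c(bernhardi = 5, cupreus = 14, hoffmannsi = 12,
                   moloch = 16, nigrifrons = 8, personatus = 16),
    Cacajao = c(calvus = 14, melanocephalus = 9),
    Chiropotes = c(albinasus = 18, satanas = 15),
    Pithecia = c(irrorata = 17, monachus = 7, pithecia = 16),
    Lagothrix = c(cana = 7, lagotricha = 8),
    Brachyteles = c(arachnoides = 16, hypoxanthus = 5),
    Ateles = c(belzebuth = 2, chamek = 15, marginatus = 20),
    Alouatta = c(belzebul = 15, caraya = 15, discolor = 10, guariba = 5,
                 guariba_clamitans = 15, nigerrima = 10, palliata = 15,
                 seniculus = 15, ululata = 7)
  )
  rows <- do.call(rbind, lapply(names(sp), function(g) {
    data.frame(species = paste(g, names(sp[[g]]), sep = "_"), genus = g,
               n = as.integer(sp[[g]]), stringsAsFactors = FALSE,
               row.names = NULL)
  }))
  merge(rows, gmap, by = "genus", sort = FALSE)[
    , c("species", "genus", "subfamily_G", "subfamily_R", "family", "n")]
}

#' Specification of a synthetic landmark dataset
#'
#' Collects the parameters of the hierarchical generative model used by
#' [generate_dataset()]: group mean shapes are the template plus smooth
#' (thin-plate-spline interpolated) displacement fields drawn once per
#' taxon at each level, with magnitudes `delta * weights[level]`;
#' individual specimens add isotropic landmark noise `sigma`. All
#' magnitudes are in unit-centroid-size shape units.
#'
#' @param taxonomy species-level table as from [platyrrhine_taxonomy()]
#'   (columns `species`, `genus`, `subfamily_G`, `subfamily_R`, `family`,
#'   `n`).
#' @param delta overall between-group effect magnitude (shape units).
#' @param sigma within-species isotropic landmark noise SD (shape units).
#' @param weights named level weights multiplying `delta`.
#' @param n_fossils number of out-of-sample "fossil" configurations.
#' @param fossil_model how fossils are built: at the centroid of a random
#'   genus, interpolated between two genus centroids, or offset to a novel
#'   shape outside the extant structure.
#' @param digit_sigma digitizing-error scale stored for repetition studies.
#' @param tooth tooth label for the emitted configurations.
#' @param p_left probability a specimen is emitted as a left-side
#'   (mirrored, index-remapped) configuration.
#' @return A list of class `"synth_spec"`.
#' @export
synth_spec <- function(taxonomy = platyrrhine_taxonomy(),
                       delta = 0.08, sigma = 0.02,
                       weights = c(family = 1.0, subfamily = 0.6,
                                   genus = 0.35, species = 0.2),
                       n_fossils = 13L,
                       fossil_model = c("centroid_of_group",
                                        "interpolation_between_groups",
                                        "offset_novel"),
                       digit_sigma = 0.01, tooth = "M1", p_left = 0.3) {
  fossil_model <- match.arg(fossil_model)
  stopifnot(delta >= 0, sigma >= 0, digit_sigma >= 0,
            all(taxonomy$n >= 1L))
  structure(list(taxonomy = taxonomy, delta = delta, sigma = sigma,
                 weights = weights, n_fossils = as.integer(n_fossils),
                 fossil_model = fossil_model, digit_sigma = digit_sigma,
                 tooth = tooth, p_left = p_left),
            class = "synth_spec")
}

# Smooth displacement field: displace a random subset of landmarks and
# interpolate with a thin-plate spline. The similarity components of the
# field (translation, rotation, rescaling of the template) are projected
# out — superimposition would remove them anyway — and the remaining
# shape-changing field is rescaled so its flattened Euclidean norm equals
# `magnitude`; `magnitude` is therefore a true shape-space effect size.
smooth_offset <- function(template, magnitude) {
  if (magnitude == 0) return(template * 0)
  k <- nrow(template)
  m <- sample(6:10, 1L)
  anchors <- sample.int(k, m)
  disp_anchor <- matrix(stats::rnorm(2L * m), m, 2L)
  fit <- tps_solve(template[anchors, , drop = FALSE],
                   template[anchors, , drop = FALSE] + 0.1 * disp_anchor)
  disp <- tps_apply(fit, template) - template
  v <- flatten_shape(disp)
  # orthonormal basis of the similarity directions at the template
  basis <- cbind(rep(c(1, 0), k), rep(c(0, 1), k),
                 flatten_shape(template),
                 flatten_shape(template %*% rot2(pi / 2)))
  basis <- qr.Q(qr(basis))
  v <- v - basis %*% crossprod(basis, v)
  unflatten_shape(v / sqrt(sum(v^2)) * magnitude)
}

# Random similarity transform + optional left-side emission of a
# unit-scale shape; returns a landmark_config in "image units".
emit_config <- function(shape, id, tooth, p_left, fossil = FALSE) {
  theta <- stats::runif(1, 0, 2 * pi)
  size_mm <- stats::rnorm(1, mean = 5, sd = 0.4)  # crown ~5 mm
  scale <- stats::runif(1, 0.01, 0.05)            # mm per image unit
  lm <- shape %*% rot2(theta) * size_mm / scale
  lm <- sweep(lm, 2L, abs(stats::rnorm(2, 50, 10)) - apply(lm, 2L, min), `+`)
  side <- if (stats::runif(1) < p_left) "left" else "right"
  if (side == "left") {
    # inverse of standardize_side(): un-remap indices, reflect, shift
    lm <- lm[mirror_pairs(), , drop = FALSE]
    lm[, 2] <- -lm[, 2]
    lm <- sweep(lm, 2L, apply(lm, 2L, min))
  }
  landmark_config(lm, id = id, tooth = tooth, side = side, scale = scale,
                  fossil = fossil)
}

#' Generate a synthetic landmark dataset with known truth
#'
#' Draws a complete landmark dataset under the hierarchical shape model of
#' [synth_spec()]: per-taxon smooth mean-shape offsets at the family,
#' subfamily (eight-scheme), genus and species levels; isotropic
#' within-species landmark noise; out-of-sample fossil configurations per
#' the chosen fossil model; and, for every specimen, a random rotation,
#' translation, size, image scale and side (left specimens are emitted
#' mirrored with remapped landmark order), so that side/scale
#' standardization and superimposition are exercised end to end. With a
#' fixed seed the output is bit-identical across runs.
#'
#' @param spec a [synth_spec()].
#' @param seed integer seed; all randomness flows from it through a local
#'   RNG stream.
#' @return A list with `dataset` (a [shape_dataset()]), and `truth`
#'   (template, per-species true mean shapes, per-specimen labels, fossil
#'   recipes).
#' @export
generate_dataset <- function(spec = synth_spec(), seed = 1L) {
  stopifnot(inherits(spec, "synth_spec"))
  with_seed(seed, {
    template <- molar_template()
    tax <- spec$taxonomy
    w <- spec$weights
    offset_for <- function(labels, magnitude) {
      out <- lapply(unique(labels), function(u) smooth_offset(template,
                                                              magnitude))
      names(out) <- unique(labels)
      out
    }
    off_fam <- offset_for(tax$family, spec$delta * w[["family"]])
    off_sub <- offset_for(tax$subfamily_G, spec$delta * w[["subfamily"]])
    off_gen <- offset_for(tax$genus, spec$delta * w[["genus"]])
    off_spe <- offset_for(tax$species, spec$delta * w[["species"]])
    species_mean <- lapply(seq_len(nrow(tax)), function(i)
      template + off_fam[[tax$family[i]]] + off_sub[[tax$subfamily_G[i]]] +
        off_gen[[tax$genus[i]]] + off_spe[[tax$species[i]]])
    names(species_mean) <- tax$species
    genus_mean <- lapply(unique(tax$genus), function(g) {
      i <- which(tax$genus == g)[1]
      template + off_fam[[tax$family[i]]] + off_sub[[tax$subfamily_G[i]]] +
        off_gen[[g]]
    })
    names(genus_mean) <- unique(tax$genus)

    configs <- list()
    tax_rows <- list()
    for (i in seq_len(nrow(tax))) {
      for (j in seq_len(tax$n[i])) {
        id <- sprintf("%s_%02d", tax$species[i], j)
        shape <- species_mean[[i]] +
          matrix(stats::rnorm(30, sd = spec$sigma), ncol = 2L)
        configs[[id]] <- emit_config(shape, id, spec$tooth, spec$p_left)
        tax_rows[[id]] <- data.frame(
          specimen_id = id, species = tax$species[i], genus = tax$genus[i],
          subfamily_G = tax$subfamily_G[i], subfamily_R = tax$subfamily_R[i],
          family = tax$family[i], fossil_flag = FALSE,
          fossil_code = NA_character_, stringsAsFactors = FALSE)
      }
    }
    recipes <- list()
    if (spec$n_fossils > 0L) {
      for (f in seq_len(spec$n_fossils)) {
        code <- sprintf("F%d", f)
        id <- sprintf("fossil_%s", code)
        src <- sample(names(genus_mean), 2L)
        shape <- switch(spec$fossil_model,
          centroid_of_group = genus_mean[[src[1]]],
          interpolation_between_groups =
            (genus_mean[[src[1]]] + genus_mean[[src[2]]]) / 2,
          offset_novel = template + smooth_offset(template, spec$delta))
        shape <- shape + matrix(stats::rnorm(30, sd = spec$sigma), ncol = 2L)
        configs[[id]] <- emit_config(shape, id, spec$tooth, spec$p_left,
                                     fossil = TRUE)
        tax_rows[[id]] <- data.frame(
          specimen_id = id, species = NA_character_, genus = NA_character_,
          subfamily_G = NA_character_, subfamily_R = NA_character_,
          family = NA_character_, fossil_flag = TRUE, fossil_code = code,
          stringsAsFactors = FALSE)
        recipes[[code]] <- data.frame(
          fossil_code = code, specimen_id = id, model = spec$fossil_model,
          source_genus = src[1],
          source_genus_2 = if (spec$fossil_model ==
                               "interpolation_between_groups") src[2]
                           else NA_character_,
          stringsAsFactors = FALSE)
      }
    }
    taxonomy <- do.call(rbind, c(tax_rows, list(make.row.names = FALSE)))
    truth <- list(template = template, species_mean = species_mean,
                  genus_mean = genus_mean,
                  fossil_recipes = if (length(recipes))
                    do.call(rbind, c(recipes, list(make.row.names = FALSE))),
                  spec = spec, seed = seed)
    list(dataset = shape_dataset(configs, taxonomy, tooth = spec$tooth),
         truth = truth)
  })
}

#' Standardize every configuration of a dataset
#'
#' Applies [standardize_side()] and [apply_scale()] to each configuration,
#' the normal preprocessing before [gpa()].
#'
#' @param dataset a [shape_dataset()].
#' @return The standardized dataset (all right-sided, scale 1, mm units).
#' @export
standardize_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "shape_dataset"))
  dataset$configs <- lapply(dataset$configs, function(cf)
    apply_scale(standardize_side(cf)))
  dataset$info$side <- "right"
  dataset$info$scale <- 1
  dataset
}

#' Generate a repeated-digitization study
#'
#' Emulates an intra-observer error study: each base specimen is
#' re-digitized `n_rep` times with independent isotropic landmark noise of
#' SD `digit_sigma` (in the base configuration's coordinate units), with
#' session (day) labels assigned in three blocks.
#'
#' @param base a [landmark_config()] or k x 2 matrix, or a list of them
#'   (one per specimen).
#' @param n_rep repetitions per specimen (>= 2).
#' @param digit_sigma digitizing noise SD.
#' @param seed integer seed (local RNG stream).
#' @return A [repetition_study()].
#' @export
generate_repetition_study <- function(base, n_rep = 9L, digit_sigma = 0.01,
                                      seed = 1L) {
  if (!is.list(base) || inherits(base, "landmark_config")) base <- list(base)
  if (n_rep < 2L) stop("n_rep must be at least 2")
  base <- lapply(base, function(b)
    if (inherits(b, "landmark_config")) b$landmarks else as_shape_matrix(b))
  if (is.null(names(base))) names(base) <- sprintf("spec%d", seq_along(base))
  days <- rep(1:3, each = ceiling(n_rep / 3))[seq_len(n_rep)]
  with_seed(seed, {
    configs <- list()
    specimen <- character(0)
    repi <- integer(0)
    day <- integer(0)
    for (sp in names(base)) {
      k <- nrow(base[[sp]])
      for (r in seq_len(n_rep)) {
        id <- sprintf("%s_rep%d", sp, r)
        lm <- base[[sp]] + matrix(stats::rnorm(2L * k, sd = digit_sigma),
                                  ncol = 2L)
        configs[[id]] <- landmark_config(lm, id = id, tooth = "M1",
                                         side = "right", scale = 1)
        specimen <- c(specimen, sp)
        repi <- c(repi, r)
        day <- c(day, days[r])
      }
    }
    repetition_study(configs, specimen, repi, day)
  })
}
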