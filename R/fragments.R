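#' Pair of disarticulated cranial fragments
#'
#' Two landmark configurations with disjoint landmark name sets (e.g. a
#' fronto-facial block and a basal-posterior block), each optionally carrying
#' its surface mesh in the same specimen frame.
#'
#' @param frag_a,frag_b [landmark_config]s with disjoint names, >= 4 landmarks
#'   each.
#' @param mesh_a,mesh_b optional [trimesh]es in the corresponding frames.
#' @return object of class `fragment_pair`.
#' @export
fragment_pair <- function(frag_a, frag_b, mesh_a = NULL, mesh_b = NULL) {
  if (length(intersect(frag_a$landmark_names, frag_b$landmark_names)))
    stop("fragments must have disjoint landmark names")
  if (nrow(frag_a$coords) < 4L || nrow(frag_b$coords) < 4L)
    stop("each fragment needs at least 4 landmarks")
  structure(list(frag_a = frag_a, frag_b = frag_b,
                 mesh_a = mesh_a, mesh_b = mesh_b),
            class = "fragment_pair")
}

#' @export
print.fragment_pair <- function(x, ...) {
  cat(sprintf("<fragment_pair> %s: %d + %d landmarks%s\n", x$frag_a$specimen_id,
              nrow(x$frag_a$coords), nrow(x$frag_b$coords),
              if (!is.null(x$mesh_a) || !is.null(x$mesh_b)) " (with meshes)" else ""))
  invisible(x)
}

# Symmetrise when the configuration supports it (pairing with >= 3 midline
# landmarks); otherwise return unchanged. Reference ranking symmetrises
# whatever sub-configuration allows it.
symmetrise_if_possible <- function(config) {
  ok <- !is.null(config$pairing) && length(config$pairing$midline) >= 3L &&
    !any(config$missing)
  if (ok) tryCatch(symmetrise(config), error = function(e) config) else config
}

# Distance of one fragment to the matching sub-configuration of a reference:
# symmetrise both, scale the reference to the fragment's centroid size,
# rigid Procrustes registration, then cumulative Euclidean + Procrustes
# distances.
fragment_reference_distance <- function(frag, reference) {
  ref_sub <- subset_config(reference, frag$landmark_names)
  frag_s <- symmetrise_if_possible(frag)
  ref_s <- symmetrise_if_possible(ref_sub)
  s <- centroid_size(frag_s) / centroid_size(ref_s)
  ref_scaled <- set_coords(ref_s, ref_s$coords * s)
  fit <- opa_align(ref_scaled, frag_s, allow_scaling = FALSE)
  c(euclidean = cumulative_euclidean_distance(fit$aligned, frag_s),
    procrustes = procrustes_distance(fit$aligned, frag_s))
}

#' Rank reference specimens by morphological affinity to a fragment pair
#'
#' For every complete reference, both fragments are compared to the matching
#' reference sub-configurations (symmetrisation, size-matching, rigid
#' Procrustes registration, then cumulative Euclidean and Procrustes
#' distances). References are ranked by the combined score, the sum of the two
#' fragments' cumulative Euclidean distances; ties break on the Procrustes
#' sum, then on reference id.
#'
#' @param pair a [fragment_pair].
#' @param references list of complete [landmark_config]s covering both
#'   fragments' landmark names.
#' @return data.frame of class `reference_ranking` with columns
#'   `reference_id, euclidean_a, euclidean_b, procrustes_a, procrustes_b,
#'   combined_score, rank`, sorted by rank.
#' @export
rank_references <- function(pair, references) {
  need <- c(pair$frag_a$landmark_names, pair$frag_b$landmark_names)
  rows <- list()
  for (ref in references) {
    if (!all(need %in% ref$landmark_names) || any(ref$missing)) {
      warning("reference '", ref$specimen_id,
              "' skipped (incomplete or missing required landmarks)")
      next
    }
    da <- fragment_reference_distance(pair$frag_a, ref)
    db <- fragment_reference_distance(pair$frag_b, ref)
    rows[[length(rows) + 1L]] <- data.frame(
      reference_id = ref$specimen_id,
      euclidean_a = da[["euclidean"]], euclidean_b = db[["euclidean"]],
      procrustes_a = da[["procrustes"]], procrustes_b = db[["procrustes"]],
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no usable reference specimens")
  tab <- do.call(rbind, rows)
  tab$combined_score <- tab$euclidean_a + tab$euclidean_b
  ord <- order(tab$combined_score, tab$procrustes_a + tab$procrustes_b,
               tab$reference_id)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  class(tab) <- c("reference_ranking", "data.frame")
  tab
}

# Combined size of a fragment pair, invariant to each fragment's pose:
# root of the pooled squared deviations about the per-fragment centroids.
combined_centroid_size <- function(a, b) sqrt(centroid_size(a)^2 + centroid_size(b)^2)

#' Re-assemble two disarticulated fragments on a reference template
#'
#' The reference is scaled once so that its two matching sub-configurations
#' jointly match the combined fragment size; each fragment is then registered
#' onto its reference sub-configuration by rotation and translation only (both
#' fragments belong to one individual, so no per-fragment scaling). The merged
#' configuration is the union of the transformed fragments in the reference
#' frame; the returned transforms can be applied to the fragment meshes.
#'
#' @param pair a [fragment_pair].
#' @param reference complete [landmark_config] covering both fragments.
#' @return list with `merged` ([landmark_config]), `transform_a`,
#'   `transform_b` ([similarity_transform]s, unit scale), `mesh_a`, `mesh_b`
#'   (transformed meshes when present in the pair) and `scale` (the reference
#'   scale factor used).
#' @export
align_fragments <- function(pair, reference) {
  need <- c(pair$frag_a$landmark_names, pair$frag_b$landmark_names)
  if (!all(need %in% reference$landmark_names) || any(reference$missing))
    stop("reference must be complete over both fragments' landmarks")
  ref_a <- subset_config(reference, pair$frag_a$landmark_names)
  ref_b <- subset_config(reference, pair$frag_b$landmark_names)
  s <- combined_centroid_size(pair$frag_a, pair$frag_b) /
    combined_centroid_size(ref_a, ref_b)
  ref_a <- set_coords(ref_a, ref_a$coords * s)
  ref_b <- set_coords(ref_b, ref_b$coords * s)
  fa <- opa_align(pair$frag_a, ref_a, allow_scaling = FALSE)
  fb <- opa_align(pair$frag_b, ref_b, allow_scaling = FALSE)
  merged <- landmark_config(rbind(fa$aligned$coords, fb$aligned$coords),
                            c(pair$frag_a$landmark_names, pair$frag_b$landmark_names),
                            specimen_id = paste0(pair$frag_a$specimen_id, "_merged"))
  list(merged = merged, transform_a = fa$transform, transform_b = fb$transform,
       mesh_a = if (!is.null(pair$mesh_a)) {
         m <- pair$mesh_a; m$vertices <- apply_transform(fa$transform, m$vertices); m
       },
       mesh_b = if (!is.null(pair$mesh_b)) {
         m <- pair$mesh_b; m$vertices <- apply_transform(fb$transform, m$vertices); m
       },
       scale = s)
}

#' Virtual reconstruction of a fragmented specimen from one or more templates
#'
#' For each template: complete any missing fragment landmarks from the
#' template (TPS estimation), re-assemble the fragments on it with
#' [align_fragments()], and record provenance.
#'
#' @param pair a [fragment_pair].
#' @param templates a single complete [landmark_config] or a list of them
#'   (e.g. the best-ranked reference, another candidate, and a group mean).
#' @return list of reconstruction bundles, one per template, each with
#'   elements `template_id`, `merged`, `transform_a`, `transform_b`, `mesh_a`,
#'   `mesh_b`.
#' @export
reconstruct_specimen <- function(pair, templates) {
  if (inherits(templates, "landmark_config")) templates <- list(templates)
  if (!length(templates)) stop("at least one template is required")
  lapply(templates, function(tpl) {
    fa <- pair$frag_a; fb <- pair$frag_b
    if (any(fa$missing)) fa <- estimate_missing_landmarks(fa, subset_config(tpl, fa$landmark_names))
    if (any(fb$missing)) fb <- estimate_missing_landmarks(fb, subset_config(tpl, fb$landmark_names))
    completed <- fragment_pair(fa, fb, pair$mesh_a, pair$mesh_b)
    out <- align_fragments(completed, tpl)
    out$template_id <- tpl$specimen_id
    out
  })
}
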