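#' Dihedral binning thresholds
#'
#' Mean inter-tier dihedral above `eclipsed_min` bins a ring as eclipsed;
#' below `staggered_max` as staggered; the band in between is reported as
#' indeterminate rather than force-binned.
#'
#' @param eclipsed_min degrees (default -15).
#' @param staggered_max degrees (default -25).
#' @return list of the two thresholds.
#' @export
dihedral_criteria <- function(eclipsed_min = -15, staggered_max = -25) {
  stopifnot(staggered_max <= eclipsed_min)
  list(eclipsed_min = eclipsed_min, staggered_max = staggered_max)
}

#' Tier centroids of a two-tier hexamer
#'
#' N-tier centroid: centroid of all OB-fold CA positions pooled across the
#' six subunits; C-tier centroid: likewise for the 152-residue AAA+ cores.
#' In direct mode each chain's own CAs within the anchor-set residue spans
#' are pooled (requires `ob_ranges`/`core_ranges` in the anchor set).  In
#' template mode a reference OB-fold and core (one chain of a template
#' model) are rigid-fit onto each subunit and the transformed copies are
#' pooled, which also transfers the dihedral anchor points; this supports
#' subunits whose own residue numbering has no shipped spans (eukaryotes).
#'
#' @param model a `StructureModel`.
#' @param ring a `RingMap` (six positions).
#' @param anchors an `AnchorSet`.
#' @param template optional list(model=, chain=) naming the template chain;
#'   NULL for direct mode.
#' @param correspondence optional named list (by subunit label) of data.frames
#'   with columns `template_resno`, `target_resno` for template mode; default
#'   identity (same author numbers as the template).
#' @param min_coverage minimum fraction of span residues that must resolve
#'   per chain (default 0.9); fewer OB-folds than six is an error.
#' @return list with `n_tier_centroid`, `c_tier_centroid` and (template mode)
#'   per-chain transferred anchor coordinates.
#' @export
tier_centroids <- function(model, ring, anchors, template = NULL,
                           correspondence = NULL, min_coverage = 0.9) {
  stopifnot(inherits(ring, "RingMap"))
  if (nrow(ring) != 6L) stop("tier_centroids: ring must be hexameric")
  if (is.null(template)) {
    pools <- direct_tier_pools(model, ring, anchors, min_coverage)
  } else {
    pools <- template_tier_pools(model, ring, anchors, template,
                                 correspondence, min_coverage)
  }
  out <- list(n_tier_centroid = centroid(pools$ob),
              c_tier_centroid = centroid(pools$core))
  out$anchor_xyz <- pools$anchor_xyz
  out
}

direct_tier_pools <- function(model, ring, anchors, min_coverage) {
  ob <- list(); core <- list()
  for (p in seq_len(nrow(ring))) {
    su <- subunit_anchors(anchors, ring$subunit[p])
    if (is.null(su$ob_ranges) || is.null(su$core_ranges))
      stop("tier_centroids: anchor set lacks ob/core ranges for subunit '",
           ring$subunit[p], "'; use template mode")
    ch <- ring$chain[p]
    m_ob <- chain_ca_in_ranges(model, ch, su$ob_ranges)
    m_core <- chain_ca_in_ranges(model, ch, su$core_ranges)
    if (nrow(m_ob) < ceiling(min_coverage * 107))
      stop("tier_centroids: OB-fold of chain '", ch, "' resolves only ",
           nrow(m_ob), " of 107 CA; six OB-folds are required")
    if (nrow(m_core) < ceiling(min_coverage * 152))
      stop("tier_centroids: AAA+ core of chain '", ch, "' resolves only ",
           nrow(m_core), " of 152 CA")
    ob[[p]] <- m_ob; core[[p]] <- m_core
  }
  list(ob = do.call(rbind, ob), core = do.call(rbind, core),
       anchor_xyz = NULL)
}

template_tier_pools <- function(model, ring, anchors, template,
                                correspondence, min_coverage) {
  tm <- template$model; tch <- template$chain
  tsu_label <- NULL
  # template chain anchors: use the anchor entry whose label matches the
  # template chain's subunit in its own ring, falling back to the first
  tsu <- anchors$subunits[[1]]
  t_ob <- chain_ca_in_ranges(tm, tch, tsu$ob_ranges)
  t_core <- chain_ca_in_ranges(tm, tch, tsu$core_ranges)
  if (nrow(t_ob) < 107 || nrow(t_core) < 152)
    stop("tier_centroids: template chain '", tch, "' is incomplete")
  t_obanchor <- get_calpha(tm, tch, tsu$ob_anchor)
  t_aaanchor <- get_calpha(tm, tch, tsu$aaa_anchor)
  ob <- list(); core <- list(); anchor_xyz <- list()
  for (p in seq_len(nrow(ring))) {
    ch <- ring$chain[p]
    map <- NULL
    if (!is.null(correspondence)) map <- correspondence[[ring$subunit[p]]]
    fit1 <- fit_template(t_ob, model, ch, map, min_coverage, "OB-fold")
    fit2 <- fit_template(t_core, model, ch, map, min_coverage, "AAA+ core")
    ob[[p]] <- apply_transform(fit1$tr, t_ob)
    core[[p]] <- apply_transform(fit2$tr, t_core)
    anchor_xyz[[ch]] <- list(
      ob_anchor = as.numeric(apply_transform(fit1$tr, rbind(t_obanchor))),
      aaa_anchor = as.numeric(apply_transform(fit2$tr, rbind(t_aaanchor))))
  }
  list(ob = do.call(rbind, ob), core = do.call(rbind, core),
       anchor_xyz = anchor_xyz)
}

# Rigid-fit a template CA set (rownames = template resno) onto one chain.
fit_template <- function(t_xyz, model, chain, map, min_coverage, what) {
  t_res <- as.integer(rownames(t_xyz))
  if (is.null(map)) {
    target_res <- t_res
  } else {
    target_res <- map$target_resno[match(t_res, map$template_resno)]
  }
  a <- model$atoms
  sel <- a$chain == chain & a$elety == "CA"
  have <- stats::setNames(seq_len(sum(sel)), a$resno[sel])
  idx <- match(as.character(target_res), names(have))
  ok <- !is.na(idx) & !is.na(target_res)
  if (sum(ok) < ceiling(min_coverage * nrow(t_xyz)))
    stop("tier_centroids: ", what, " of chain '", chain,
         "' resolves only ", sum(ok), " of ", nrow(t_xyz),
         " corresponding CA")
  tgt <- as.matrix(a[sel, c("x", "y", "z")])[idx[ok], , drop = FALSE]
  tr <- superpose(tgt, t_xyz[ok, , drop = FALSE])
  list(tr = tr, fit_rmsd = tr$rmsd)
}

#' Inter-tier dihedral of one subunit
#'
#' Four-point torsion: OB anchor CA, N-tier centroid, C-tier centroid, AAA+
#' anchor CA.  A 0 degree dihedral aligns the subunit's N-tier and C-tier
#' interface seams (eclipsed); negative values rotate the C-tier anchor
#' clockwise (viewed from the N-side) into the staggered regime.
#'
#' @inheritParams tier_centroids
#' @param chain chain identifier of the subunit.
#' @param tiers optional precomputed [tier_centroids()] result.
#' @return dihedral in degrees.
#' @export
subunit_dihedral <- function(model, ring, anchors, chain, tiers = NULL,
                             template = NULL, correspondence = NULL) {
  if (is.null(tiers))
    tiers <- tier_centroids(model, ring, anchors, template, correspondence)
  p <- match(chain, ring$chain)
  if (is.na(p)) stop("subunit_dihedral: chain '", chain, "' not in ring")
  if (!is.null(tiers$anchor_xyz)) {
    p1 <- tiers$anchor_xyz[[chain]]$ob_anchor
    p4 <- tiers$anchor_xyz[[chain]]$aaa_anchor
  } else {
    su <- subunit_anchors(anchors, ring$subunit[p])
    if (is.null(su$ob_anchor) || is.null(su$aaa_anchor))
      stop("subunit_dihedral: anchor set lacks dihedral anchors for '",
           ring$subunit[p], "'")
    p1 <- get_calpha(model, chain, su$ob_anchor)
    p4 <- get_calpha(model, chain, su$aaa_anchor)
  }
  dihedral_angle(p1, tiers$n_tier_centroid, tiers$c_tier_centroid, p4)
}

#' Mean dihedral and eclipsed/staggered class
#'
#' Arithmetic mean of the per-subunit dihedrals after wrapping each into
#' (-180, 180], then binned by [dihedral_criteria()].
#'
#' @param per_subunit named numeric vector of per-subunit dihedrals (degrees).
#' @param criteria a [dihedral_criteria()] list.
#' @return a `DihedralResult`: list with `per_subunit`, `mean_dihedral`,
#'   `tier_class` ("eclipsed", "staggered" or "indeterminate").
#' @export
mean_and_classify <- function(per_subunit, criteria = dihedral_criteria()) {
  if (length(per_subunit) < 1L) stop("mean_and_classify: no dihedrals")
  per_subunit <- wrap_angle(per_subunit)
  m <- mean(per_subunit)
  cls <- if (m > criteria$eclipsed_min) "eclipsed"
         else if (m < criteria$staggered_max) "staggered"
         else "indeterminate"
  structure(list(per_subunit = per_subunit, mean_dihedral = m,
                 tier_class = cls, criteria = criteria),
            class = "DihedralResult")
}

#' Per-subunit inter-tier dihedrals of a whole ring
#'
#' Computes the subunit dihedral for every ring chain (omitting, with a
#' record, chains whose anchors do not resolve), the mean and the
#' eclipsed/staggered class.
#'
#' @inheritParams tier_centroids
#' @param criteria a [dihedral_criteria()] list.
#' @return a `DihedralResult` with an extra `omitted` field naming chains
#'   whose dihedral could not be computed.
#' @export
ring_dihedral <- function(model, ring, anchors, template = NULL,
                          correspondence = NULL,
                          criteria = dihedral_criteria()) {
  tiers <- tier_centroids(model, ring, anchors, template, correspondence)
  vals <- c(); omitted <- character(0)
  for (ch in ring$chain) {
    v <- tryCatch(subunit_dihedral(model, ring, anchors, ch, tiers = tiers),
                  error = function(e) NA_real_)
    if (is.na(v)) omitted <- c(omitted, ch)
    else vals[ch] <- v
  }
  if (!length(vals))
    stop("ring_dihedral: no subunit dihedral could be computed")
  out <- mean_and_classify(vals, criteria)
  out$omitted <- omitted
  out$model_id <- model$id
  out
}

#' @export
print.DihedralResult <- function(x, ...) {
  if (!is.null(x$model_id)) cat("Model '", x$model_id, "'\n", sep = "")
  cat("Per-subunit dihedrals (deg):\n")
  print(round(x$per_subunit, 2))
  cat(sprintf("mean %.2f deg -> %s\n", x$mean_dihedral, x$tier_class))
  if (length(x$omitted))
    cat("omitted chains:", paste(x$omitted, collapse = ", "), "\n")
  invisible(x)
}
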