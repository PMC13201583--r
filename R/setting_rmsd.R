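#' Extract a 152-residue AAA+ core template from one chain
#'
#' @param model a `StructureModel`.
#' @param chain chain identifier.
#' @param anchors an `AnchorSet` whose subunit entry carries `core_ranges`.
#' @param subunit anchor-set subunit label (default first).
#' @return matrix 152 x 3 of CA coordinates, rownames = residue numbers.
#' @export
core_template <- function(model, chain, anchors,
                          subunit = names(anchors$subunits)[1]) {
  su <- subunit_anchors(anchors, subunit)
  if (is.null(su$core_ranges))
    stop("core_template: anchor set lacks core_ranges for '", subunit, "'")
  m <- chain_ca_in_ranges(model, chain, su$core_ranges)
  if (nrow(m) != 152)
    stop("core_template: chain '", chain, "' resolves ", nrow(m),
         " of 152 core CA; a complete template chain is required")
  m
}

#' Build an idealized core hexamer by template placement
#'
#' Rigid-fits one 152-residue AAA+ core template onto each of the six ring
#' chains (by CA correspondence) and stores the transformed full template
#' copy for every chain, so all six copies are exact rigid copies of the
#' template.  Chains may be incomplete: at least `min_coverage` of the 152
#' corresponding CAs must resolve (missing pairs are dropped from the fit
#' but the stored copy is always the full template).
#'
#' @param model a `StructureModel`.
#' @param ring a six-position `RingMap`.
#' @param template a 152 x 3 CA matrix from [core_template()] (rownames =
#'   template residue numbers).
#' @param correspondence optional named list (by subunit label) of data.frames
#'   `template_resno` / `target_resno`; default identity numbering.
#' @param min_coverage minimum resolvable CAs per chain (default 140).
#' @return a `CoreHexamer`: list with `source_id`, `ring`, `copies` (list of
#'   six 152 x 3 matrices in ring order) and `fit_rmsd` (per-copy fit RMSD).
#' @export
build_core_hexamer <- function(model, ring, template, correspondence = NULL,
                               min_coverage = 140) {
  stopifnot(inherits(ring, "RingMap"))
  if (nrow(ring) != 6L) stop("build_core_hexamer: ring must be hexameric")
  if (nrow(template) != 152)
    stop("build_core_hexamer: template must have 152 CA positions")
  copies <- vector("list", 6L); fit_rmsd <- numeric(6L)
  for (p in seq_len(6L)) {
    ch <- ring$chain[p]
    map <- NULL
    if (!is.null(correspondence)) {
      map <- correspondence[[ring$subunit[p]]]
      if (is.null(map))
        stop("build_core_hexamer: no residue correspondence for subunit '",
             ring$subunit[p], "'")
    }
    fit <- fit_template(template, model, ch, map,
                        min_coverage / nrow(template), "AAA+ core")
    copies[[p]] <- apply_transform(fit$tr, template)
    fit_rmsd[p] <- fit$fit_rmsd
  }
  structure(list(source_id = model$id, ring = ring, copies = copies,
                 fit_rmsd = fit_rmsd),
            class = "CoreHexamer")
}

#' RMSD between two core hexamers in one cyclic setting
#'
#' Setting s pairs target ring position i with reference position
#' i + (s - 1) (mod 6).  All 6 x 152 = 912 CA pairs are put in
#' correspondence, globally superposed as a single unit, and the minimized
#' RMSD of that one fit is returned (not a per-copy average).
#'
#' @param reference,target `CoreHexamer` objects.
#' @param setting integer 1-6.
#' @return RMSD in Angstrom.
#' @export
setting_rmsd <- function(reference, target, setting) {
  stopifnot(inherits(reference, "CoreHexamer"), inherits(target, "CoreHexamer"))
  if (!setting %in% 1:6) stop("setting_rmsd: setting must be 1-6")
  ref_idx <- ((seq_len(6L) - 1L + (setting - 1L)) %% 6L) + 1L
  ref_pts <- do.call(rbind, reference$copies[ref_idx])
  tgt_pts <- do.call(rbind, target$copies)
  superpose(ref_pts, tgt_pts)$rmsd
}

#' RMSD of a target against a reference in all six settings
#'
#' @param reference,target `CoreHexamer` objects.
#' @return a `SettingRmsdTable`: list with `rmsd_by_setting` (named numeric,
#'   settings 1-6), `best_setting` (argmin, lowest index on ties) and
#'   `best_rmsd`.
#' @export
setting_rmsd_table <- function(reference, target) {
  r <- vapply(1:6, function(s) setting_rmsd(reference, target, s), numeric(1))
  names(r) <- as.character(1:6)
  best <- which.min(r)   # which.min takes the lowest index on ties
  structure(list(reference_id = reference$source_id,
                 target_id = target$source_id,
                 rmsd_by_setting = r,
                 best_setting = as.integer(best),
                 best_rmsd = unname(r[best])),
            class = "SettingRmsdTable")
}

#' Bin and sort structures by tier class, best setting and RMSD
#'
#' Reproduces the survey ordering: structures are binned eclipsed /
#' staggered / indeterminate, sub-binned by the setting giving the lowest
#' RMSD, and each sub-bin is reverse-sorted (descending) by that lowest
#' RMSD; ties keep a stable order by structure id.
#'
#' @param records data.frame with columns `structure_id`, `mean_dihedral`,
#'   `tier_class`, `best_setting`, `best_rmsd` (see [survey_models()]), or a
#'   list of lists with those fields.
#' @return the ordered data.frame (empty input gives an empty report).
#' @export
bin_and_sort <- function(records) {
  if (is.list(records) && !is.data.frame(records)) {
    records <- do.call(rbind, lapply(records, function(r)
      data.frame(structure_id = r$structure_id,
                 mean_dihedral = r$mean_dihedral,
                 tier_class = r$tier_class,
                 best_setting = r$best_setting,
                 best_rmsd = r$best_rmsd, stringsAsFactors = FALSE)))
  }
  if (is.null(records) || nrow(records) == 0L)
    return(data.frame(structure_id = character(0),
                      mean_dihedral = numeric(0),
                      tier_class = character(0),
                      best_setting = integer(0),
                      best_rmsd = numeric(0)))
  cls <- factor(records$tier_class,
                levels = c("eclipsed", "staggered", "indeterminate"))
  ord <- order(cls, records$best_setting, -records$best_rmsd,
               records$structure_id)
  out <- records[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Survey a set of models: dihedral class plus best-fitting setting
#'
#' Runs the inter-tier dihedral statistic and the six-setting core-RMSD
#' comparison for each model against one reference hexamer and emits the
#' binned/sorted report of [bin_and_sort()].
#'
#' @param models list of `StructureModel`s.
#' @param rings list of `RingMap`s (one per model, recycled if length 1).
#' @param anchors an `AnchorSet`.
#' @param reference a `CoreHexamer` reference.
#' @param template 152 x 3 template passed to [build_core_hexamer()].
#' @param correspondence optional, see [build_core_hexamer()].
#' @return ordered data.frame (one row per model that completed both
#'   analyses; failures are dropped with a warning).
#' @export
survey_models <- function(models, rings, anchors, reference, template,
                          correspondence = NULL) {
  if (length(rings) == 1L) rings <- rep(rings, length(models))
  recs <- list()
  for (i in seq_along(models)) {
    rec <- tryCatch({
      dih <- ring_dihedral(models[[i]], rings[[i]], anchors)
      hex <- build_core_hexamer(models[[i]], rings[[i]], template,
                                correspondence)
      tab <- setting_rmsd_table(reference, hex)
      list(structure_id = models[[i]]$id,
           mean_dihedral = dih$mean_dihedral,
           tier_class = dih$tier_class,
           best_setting = tab$best_setting,
           best_rmsd = tab$best_rmsd)
    }, error = function(e) {
      warning("survey_models: skipping '", models[[i]]$id, "': ",
              conditionMessage(e))
      NULL
    })
    if (!is.null(rec)) recs[[length(recs) + 1L]] <- rec
  }
  bin_and_sort(recs)
}

#' @export
print.SettingRmsdTable <- function(x, ...) {
  cat("Setting RMSD of '", x$target_id, "' vs '", x$reference_id, "' (A):\n",
      sep = "")
  print(round(x$rmsd_by_setting, 3))
  cat(sprintf("best: setting %d (%.3f A)\n", x$best_setting, x$best_rmsd))
  invisible(x)
}

#' @export
print.CoreHexamer <- function(x, ...) {
  cat("CoreHexamer from '", x$source_id, "': 6 x 152 CA copies; ",
      "per-copy fit RMSD ",
      paste(sprintf("%.3f", x$fit_rmsd), collapse = ", "), " A\n", sep = "")
  invisible(x)
}
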