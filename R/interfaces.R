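#' Tight/loose interface criteria
#'
#' The dual distance thresholds that define a tight bipartite ATPase
#' interface: Walker-A proline CA to arginine-finger-minus-4 CA below
#' `atp_threshold`, and h2i leucine CA to ps1-beta lysine CA below
#' `h2i_threshold`.  Both inequalities are strict; an interface exactly at a
#' threshold is loose.
#'
#' @param atp_threshold ATP-site CA-CA threshold in Angstrom (default 6.8).
#' @param h2i_threshold h2i/ps1-beta CA-CA threshold in Angstrom (default 8.0).
#' @return list of the two thresholds.
#' @export
interface_criteria <- function(atp_threshold = 6.8, h2i_threshold = 8.0) {
  stopifnot(atp_threshold > 0, h2i_threshold > 0)
  list(atp_threshold = atp_threshold, h2i_threshold = h2i_threshold)
}

#' Measure one bipartite ATPase interface
#'
#' Interface at ring position i joins chain_i (Walker-A face) to chain_{i+1}
#' (arginine-finger face).  Both anchor distances are CA-CA.  If any anchor
#' CA cannot be resolved (e.g. a disordered ATPase domain) the verdict is
#' "unmeasurable" rather than loose, and the failing anchor is reported.
#'
#' @param model a `StructureModel`.
#' @param ring a `RingMap`.
#' @param anchors an `AnchorSet`.
#' @param position ring position 1-6.
#' @param criteria an [interface_criteria()] list.
#' @return an `InterfaceMeasurement`: list with chains, the two distances,
#'   `tight` (TRUE/FALSE, or NA if unmeasurable), `missing` (failed anchor or
#'   NULL) and the criteria used.
#' @export
measure_interface <- function(model, ring, anchors, position,
                              criteria = interface_criteria()) {
  stopifnot(inherits(ring, "RingMap"))
  if (position < 1L || position > nrow(ring))
    stop("measure_interface: position out of range")
  j <- ring_neighbor(ring, position)
  ch_i <- ring$chain[position]; ch_j <- ring$chain[j]
  an_i <- subunit_anchors(anchors, ring$subunit[position])
  an_j <- subunit_anchors(anchors, ring$subunit[j])
  pts <- list(
    walkerA_pro = c(ch_i, an_i$walkerA_pro),
    h2i_leu = c(ch_i, an_i$h2i_leu),
    argfinger_minus4 = c(ch_j, an_j$argfinger_minus4),
    ps1b_lys = c(ch_j, an_j$ps1b_lys))
  xyz <- list(); missing <- NULL
  for (nm in names(pts)) {
    xyz[[nm]] <- tryCatch(
      get_calpha(model, pts[[nm]][1], as.integer(pts[[nm]][2])),
      error = function(e) {
        missing <<- c(missing, paste0(nm, "@", pts[[nm]][1], "/",
                                      pts[[nm]][2]))
        NULL
      })
  }
  if (!is.null(missing)) {
    out <- list(position = position, walkerA_chain = ch_i, argF_chain = ch_j,
                atp_site_distance = NA_real_, h2i_ps1b_distance = NA_real_,
                tight = NA, missing = missing, criteria = criteria)
    return(structure(out, class = "InterfaceMeasurement"))
  }
  atp <- sqrt(sum((xyz$walkerA_pro - xyz$argfinger_minus4)^2))
  h2i <- sqrt(sum((xyz$h2i_leu - xyz$ps1b_lys)^2))
  structure(list(position = position, walkerA_chain = ch_i, argF_chain = ch_j,
                 atp_site_distance = atp, h2i_ps1b_distance = h2i,
                 tight = atp < criteria$atp_threshold &&
                   h2i < criteria$h2i_threshold,
                 missing = NULL, criteria = criteria),
            class = "InterfaceMeasurement")
}

#' Classify all six interfaces of a hexameric ring
#'
#' @inheritParams measure_interface
#' @return a `RingClassification`: list with `interfaces` (list of six
#'   `InterfaceMeasurement`s in ring order), `tight_count` (unmeasurable
#'   interfaces excluded) and `n_unmeasurable`.
#' @export
classify_ring <- function(model, ring, anchors,
                          criteria = interface_criteria()) {
  stopifnot(inherits(ring, "RingMap"))
  if (nrow(ring) != 6L) stop("classify_ring: ring must be hexameric")
  ms <- lapply(seq_len(6L), function(p)
    measure_interface(model, ring, anchors, p, criteria))
  tight <- vapply(ms, function(m) m$tight, logical(1))
  structure(list(model_id = model$id, interfaces = ms,
                 tight_count = sum(tight, na.rm = TRUE),
                 n_unmeasurable = sum(is.na(tight)),
                 criteria = criteria),
            class = "RingClassification")
}

#' Re-apply the dual thresholds to a table of printed distances
#'
#' Pure re-application of the tight/loose rule to six (ATP-site,
#' h2i-ps1-beta) distance pairs, e.g. values transcribed from a published
#' table; no coordinates required.
#'
#' @param atp_site,h2i_ps1b numeric vectors of six distances each (Angstrom).
#' @param criteria an [interface_criteria()] list.
#' @return list with `tight` (logical vector of six verdicts) and
#'   `tight_count`.
#' @export
classify_from_distance_table <- function(atp_site, h2i_ps1b,
                                         criteria = interface_criteria()) {
  if (length(atp_site) != 6L || length(h2i_ps1b) != 6L)
    stop("classify_from_distance_table: six distance pairs required")
  if (any(atp_site <= 0) || any(h2i_ps1b <= 0))
    stop("classify_from_distance_table: non-positive distance")
  tight <- atp_site < criteria$atp_threshold &
    h2i_ps1b < criteria$h2i_threshold
  list(tight = tight, tight_count = sum(tight))
}

#' Published per-interface distance table
#'
#' The CA-CA interface distances printed for the archaeal snapshot classes
#' and the comparative eukaryotic depositions (six interfaces each, ATP-site
#' and h2i-ps1-beta columns), transcribed to machine-readable form so the
#' dual-threshold rule can be re-applied without coordinates.
#'
#' @return data.frame: structure, interface, atp_site, h2i_ps1b.
#' @export
published_interface_table <- function() {
  path <- system.file("extdata", "published_interface_distances.tsv",
                      package = "ringmetrics")
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' @export
as.data.frame.RingClassification <- function(x, ...) {
  rows <- lapply(x$interfaces, function(m) {
    data.frame(position = m$position,
               interface = paste0(m$walkerA_chain, ":", m$argF_chain),
               atp_site = m$atp_site_distance,
               h2i_ps1b = m$h2i_ps1b_distance,
               verdict = if (is.na(m$tight)) "unmeasurable"
                         else if (m$tight) "tight" else "loose",
               missing = if (is.null(m$missing)) ""
                         else paste(m$missing, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a per-interface TSV report
#'
#' One row per interface (chains, distances to 3 decimals, verdict) plus a
#' summary row with the tight count.
#'
#' @param x a `RingClassification`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_interface_report <- function(x, path) {
  df <- as.data.frame(x)
  df$atp_site <- sprintf("%.3f", df$atp_site)
  df$h2i_ps1b <- sprintf("%.3f", df$h2i_ps1b)
  summary_row <- data.frame(position = NA, interface = "tight_count",
                            atp_site = "", h2i_ps1b = "",
                            verdict = as.character(x$tight_count),
                            missing = "", stringsAsFactors = FALSE)
  utils::write.table(rbind(df, summary_row), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.RingClassification <- function(x, ...) {
  cat("Ring interface classification for '", x$model_id, "':\n", sep = "")
  print(as.data.frame(x), row.names = FALSE)
  cat("tight interfaces:", x$tight_count)
  if (x$n_unmeasurable > 0)
    cat(" (", x$n_unmeasurable, " unmeasurable)", sep = "")
  cat("\n")
  invisible(x)
}

#' @export
print.InterfaceMeasurement <- function(x, ...) {
  if (is.na(x$tight)) {
    cat("Interface ", x$walkerA_chain, ":", x$argF_chain,
        " unmeasurable (", paste(x$missing, collapse = ", "), ")\n", sep = "")
  } else {
    cat(sprintf("Interface %s:%s  ATP-site %.3f A  h2i-ps1b %.3f A  -> %s\n",
                x$walkerA_chain, x$argF_chain, x$atp_site_distance,
                x$h2i_ps1b_distance, if (x$tight) "tight" else "loose"))
  }
  invisible(x)
}
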