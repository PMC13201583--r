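#' Built-in residue-anchor sets
#'
#' Loads one of the anchor tables shipped with the package: per-subunit
#' residue numbers for the four interface anchors (Walker-A proline,
#' arginine-finger-minus-4, h2i leucine, ps1-beta lysine), the two inter-tier
#' dihedral anchors, the DNA-binding donor residues and the OB-fold / AAA+
#' core residue spans.  The archaeal set is in deposited numbering and also
#' carries the construct (native) numbers; the eukaryotic sets carry the
#' published interface anchors only.
#'
#' @param name "archaeal_chimera", "ScMcm2-7" or "HsMcm2-7".
#' @return an `AnchorSet`: list with `set_name`, `ring_order` (default cyclic
#'   subunit order) and `subunits` (named list of per-subunit anchor lists).
#' @export
builtin_anchor_set <- function(name) {
  dir <- system.file("anchors", package = "ringmetrics")
  avail <- sub("\\.yaml$", "", list.files(dir, pattern = "\\.yaml$"))
  if (!name %in% avail)
    stop("unknown anchor set '", name, "'; available: ",
         paste(avail, collapse = ", "))
  read_anchor_set(file.path(dir, paste0(name, ".yaml")))
}

#' Read a user-supplied anchor set (YAML)
#'
#' @param path YAML file with keys `set_name`, `ring_order` and `subunits`
#'   (see the files under `inst/anchors/` for the schema).
#' @return an `AnchorSet`.
#' @export
read_anchor_set <- function(path) {
  raw <- yaml::read_yaml(path)
  validate_anchor_set(raw)
  structure(raw, class = "AnchorSet")
}

validate_anchor_set <- function(x) {
  if (is.null(x$subunits) || !length(x$subunits))
    stop("anchor set has no subunits")
  need <- c("walkerA_pro", "argfinger_minus4", "h2i_leu", "ps1b_lys")
  for (nm in names(x$subunits)) {
    su <- x$subunits[[nm]]
    miss <- setdiff(need, names(su))
    if (length(miss))
      stop("anchor set subunit '", nm, "' lacks interface anchors: ",
           paste(miss, collapse = ", "))
    if (!is.null(su$core_ranges)) {
      n <- sum(vapply(su$core_ranges, function(r) r[2] - r[1] + 1, numeric(1)))
      if (n != 152)
        stop("anchor set subunit '", nm, "': core_ranges cover ", n,
             " residues, expected 152")
    }
    if (!is.null(su$ob_ranges)) {
      n <- sum(vapply(su$ob_ranges, function(r) r[2] - r[1] + 1, numeric(1)))
      if (n != 107)
        stop("anchor set subunit '", nm, "': ob_ranges cover ", n,
             " residues, expected 107")
    }
  }
  invisible(x)
}

subunit_anchors <- function(anchors, label) {
  su <- anchors$subunits[[label]]
  if (is.null(su))
    stop("anchor set '", anchors$set_name, "' has no subunit '", label, "'")
  su
}

#' Cyclic ring map: chain order and subunit identities
#'
#' Fixes the direction of the ring: positions advance from the Walker-A face
#' of one subunit to the arginine-finger face of the next, so interface i is
#' chain_i : chain_{i+1} with chain_i contributing the Walker-A / h2i anchors.
#' The eukaryotic reference order around the ring is Mcm2, 6, 4, 7, 3, 5
#' (equivalent to archaeal chain positions A-F).
#'
#' @param chains character vector of chain identifiers in ring order.
#' @param subunits character vector of subunit labels (anchor-set keys), same
#'   length; defaults to "archaeal" for every position.
#' @return a `RingMap` (data.frame: position, chain, subunit).
#' @export
ring_map <- function(chains, subunits = rep("archaeal", length(chains))) {
  if (length(chains) != length(subunits))
    stop("ring_map: chains and subunits differ in length")
  if (anyDuplicated(chains)) stop("ring_map: duplicate chain identifiers")
  structure(data.frame(position = seq_along(chains),
                       chain = as.character(chains),
                       subunit = as.character(subunits),
                       stringsAsFactors = FALSE),
            class = c("RingMap", "data.frame"))
}

#' Default hexamer ring maps
#'
#' @param anchors an `AnchorSet` (its `ring_order` fixes the subunit order).
#' @param chains chain identifiers for ring positions 1-6 (default A-F).
#' @return a `RingMap` with six positions.
#' @export
default_ring_map <- function(anchors, chains = LETTERS[1:6]) {
  ord <- anchors$ring_order
  if (is.null(ord)) ord <- rep(names(anchors$subunits)[1], length(chains))
  ring_map(chains, ord)
}

#' Enumerate the six cyclic settings of a hexameric ring
#'
#' A "setting" rotates the assignment of subunit identities onto the fixed
#' chain positions.  Setting 1 is the map as given (reference order, e.g.
#' A=Mcm2, B=Mcm6, C=Mcm4, D=Mcm7, E=Mcm3, F=Mcm5); setting k advances every
#' label by k-1 positions around the ring.  Reflections are excluded: ring
#' handedness is physical.
#'
#' @param ring a six-position `RingMap`.
#' @return list of six `RingMap`s, one per setting.
#' @export
enumerate_settings <- function(ring) {
  stopifnot(inherits(ring, "RingMap"))
  n <- nrow(ring)
  if (n != 6L) stop("enumerate_settings: ring must have six positions")
  lapply(seq_len(n), function(k) {
    idx <- ((seq_len(n) - 1L + (k - 1L)) %% n) + 1L
    ring_map(ring$chain, ring$subunit[idx])
  })
}

ring_neighbor <- function(ring, position, offset = 1L) {
  n <- nrow(ring)
  ((position - 1L + offset) %% n) + 1L
}
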