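#' Geometric contact criteria for DNA pairing and engagement
#'
#' Watson-Crick pairing is called when complementary bases satisfy both a
#' C1'-C1' distance cap and a cap on the distance between the Watson-Crick
#' face nitrogens (purine N1 to pyrimidine N3).  The defaults follow
#' canonical B-DNA geometry (C1'-C1' about 10.4 A, N1-N3 about 2.9 A).
#' `engagement_max` is the donor-to-phosphate distance below which a
#' hairpin donor atom counts as engaging a nucleotide.
#'
#' @param c1c1_max Angstrom (default 11.0).
#' @param n1n3_max Angstrom (default 3.5).
#' @param engagement_max Angstrom (default 3.6).
#' @return list of the three criteria.
#' @export
contact_criteria <- function(c1c1_max = 11.0, n1n3_max = 3.5,
                             engagement_max = 3.6) {
  stopifnot(c1c1_max > 0, n1n3_max > 0, engagement_max > 0)
  list(c1c1_max = c1c1_max, n1n3_max = n1n3_max,
       engagement_max = engagement_max)
}

PURINES <- c("DA", "DG")
WC_PARTNER <- c(DA = "DT", DT = "DA", DC = "DG", DG = "DC")

dna_residues <- function(model, chain) {
  a <- model$atoms
  sel <- a$chain == chain & a$resid %in% DNA_CODES
  if (!any(sel)) stop("chain '", chain, "' has no DNA nucleotides")
  res <- unique(data.frame(resno = a$resno[sel], resid = a$resid[sel],
                           stringsAsFactors = FALSE))
  res[order(res$resno), , drop = FALSE]
}

# Watson-Crick face nitrogen: N1 for purines, N3 for pyrimidines.
wc_atom <- function(resid) ifelse(resid %in% PURINES, "N1", "N3")

#' Determine the duplex pairing register of two modeled DNA strands
#'
#' Detects Watson-Crick pairs between complementary bases that satisfy both
#' geometric criteria, takes the longest consistent antiparallel run as the
#' duplex register (`pair_map`), and reports modeled nucleotides outside it
#' whose register-implied partner is unmodeled or fails the geometry as
#' unpaired.  Unpaired nucleotides in originally fully duplex DNA are the
#' signature of melting.
#'
#' @param model a `StructureModel`.
#' @param strand_a,strand_b DNA chain identifiers (each >= 4 modeled
#'   nucleotides).
#' @param criteria a [contact_criteria()] list.
#' @return a `DuplexRegister`: list with `strand_a`, `strand_b`, `pair_map`
#'   (data.frame resnum_a, resnum_b; a ascending, b descending), `unpaired_a`,
#'   `unpaired_b` (integer vectors).
#' @export
find_register <- function(model, strand_a, strand_b,
                          criteria = contact_criteria()) {
  ra <- dna_residues(model, strand_a)
  rb <- dna_residues(model, strand_b)
  if (nrow(ra) < 4L || nrow(rb) < 4L)
    stop("find_register: both strands need at least 4 modeled nucleotides")
  geom_ok <- function(ia, ib) {
    if (WC_PARTNER[[ra$resid[ia]]] != rb$resid[ib]) return(FALSE)
    c1a <- try_atom(model, strand_a, ra$resno[ia], "C1'")
    c1b <- try_atom(model, strand_b, rb$resno[ib], "C1'")
    na <- try_atom(model, strand_a, ra$resno[ia], wc_atom(ra$resid[ia]))
    nb <- try_atom(model, strand_b, rb$resno[ib], wc_atom(rb$resid[ib]))
    if (is.null(c1a) || is.null(c1b) || is.null(na) || is.null(nb))
      return(FALSE)
    sqrt(sum((c1a - c1b)^2)) <= criteria$c1c1_max &&
      sqrt(sum((na - nb)^2)) <= criteria$n1n3_max
  }
  # candidate pairs, then longest antiparallel run (a ascending by +1 steps,
  # b descending by -1 steps)
  cand <- which(outer(seq_len(nrow(ra)), seq_len(nrow(rb)),
                      Vectorize(geom_ok)), arr.ind = TRUE)
  if (nrow(cand) == 0L)
    stop("find_register: no Watson-Crick pair found; not a duplex")
  pairs <- data.frame(resnum_a = ra$resno[cand[, 1]],
                      resnum_b = rb$resno[cand[, 2]])
  pairs <- pairs[order(pairs$resnum_a, pairs$resnum_b), , drop = FALSE]
  # antiparallel register: resnum_a + resnum_b is constant along a run
  pairs$reg <- pairs$resnum_a + pairs$resnum_b
  best <- NULL
  for (g in split(pairs, pairs$reg)) {
    g <- g[order(g$resnum_a), , drop = FALSE]
    runs <- cumsum(c(1L, diff(g$resnum_a) != 1L))
    for (r in split(g, runs)) {
      if (is.null(best) || nrow(r) > nrow(best)) best <- r
    }
  }
  pair_map <- best[, c("resnum_a", "resnum_b")]
  rownames(pair_map) <- NULL
  reg <- best$reg[1]
  paired_a <- pair_map$resnum_a; paired_b <- pair_map$resnum_b
  un_a <- integer(0); un_b <- integer(0)
  for (i in seq_len(nrow(ra))) {
    if (ra$resno[i] %in% paired_a) next
    partner <- reg - ra$resno[i]
    if (!partner %in% rb$resno ||
        !geom_ok(i, match(partner, rb$resno)))
      un_a <- c(un_a, ra$resno[i])
  }
  for (i in seq_len(nrow(rb))) {
    if (rb$resno[i] %in% paired_b) next
    partner <- reg - rb$resno[i]
    if (!partner %in% ra$resno ||
        !geom_ok(match(partner, ra$resno), i))
      un_b <- c(un_b, rb$resno[i])
  }
  structure(list(strand_a = strand_a, strand_b = strand_b,
                 pair_map = pair_map, unpaired_a = un_a, unpaired_b = un_b,
                 register = reg),
            class = "DuplexRegister")
}

try_atom <- function(model, chain, resno, elety) {
  tryCatch(get_atom_xyz(model, chain, resno, elety),
           error = function(e) NULL)
}

#' Count melted nucleotides of the tracked strand
#'
#' Number of modeled tracked-strand nucleotides whose partner is unmodeled
#' or fails the pairing geometry, contiguous with one duplex terminus (for
#' these complexes, the terminus nearest the ATPase tier, where melting
#' initiates).
#'
#' @param register a `DuplexRegister`.
#' @param tracked "a" or "b": which strand's unpaired nucleotides to count.
#' @param terminus "5prime" (low residue numbers of the tracked strand,
#'   default) or "3prime": the duplex end the melt is contiguous with.
#' @return integer count.
#' @export
melted_count <- function(register, tracked = c("a", "b"),
                         terminus = c("5prime", "3prime")) {
  tracked <- match.arg(tracked)
  terminus <- match.arg(terminus)
  un <- sort(if (tracked == "a") register$unpaired_a else register$unpaired_b)
  paired <- if (tracked == "a") register$pair_map$resnum_a
            else register$pair_map$resnum_b
  if (!length(un)) return(0L)
  if (terminus == "5prime") {
    edge <- min(paired)
    run <- rev(seq(edge - 1L, by = -1L, length.out = sum(un < edge)))
    sum(rev(un[un < edge]) == rev(run)[seq_len(sum(un < edge))])
  } else {
    edge <- max(paired)
    run <- seq(edge + 1L, by = 1L, length.out = sum(un > edge))
    sum(un[un > edge] == run[seq_len(sum(un > edge))])
  }
}

#' Count hairpin-engaged nucleotides of the tracked strand
#'
#' A nucleotide is engaged when any of its phosphate/sugar oxygens (or the
#' phosphorus itself) lies within `engagement_max` of a donor atom of the
#' DNA-binding set of any subunit: the ps1-beta lysine side-chain amine, the
#' following residue's backbone amide, the h2i hydroxyl side chain and the
#' h2i backbone amide.
#'
#' @param model a `StructureModel`.
#' @param ring a `RingMap`.
#' @param anchors an `AnchorSet` carrying the donor residue numbers
#'   (`ps1b_lys`, `ps1b_amide`, `h2i_hydroxyl`, `h2i_amide`).
#' @param strand tracked DNA chain identifier.
#' @param criteria a [contact_criteria()] list.
#' @return list with `count`, `resnums` (engaged nucleotide numbers) and
#'   `donor_contacts` (data.frame nucleotide / chain / donor / distance).
#' @export
engaged_nucleotides <- function(model, ring, anchors, strand,
                                criteria = contact_criteria()) {
  res <- dna_residues(model, strand)   # errors if no DNA
  donors <- list()
  for (p in seq_len(nrow(ring))) {
    su <- subunit_anchors(anchors, ring$subunit[p])
    ch <- ring$chain[p]
    spec <- list(
      ps1b_lys = c(su$ps1b_lys, "NZ"),
      ps1b_amide = c(su$ps1b_amide, "N"),
      h2i_hydroxyl_og = c(su$h2i_hydroxyl, "OG"),
      h2i_hydroxyl_og1 = c(su$h2i_hydroxyl, "OG1"),
      h2i_hydroxyl_oh = c(su$h2i_hydroxyl, "OH"),
      h2i_amide = c(su$h2i_amide, "N"))
    for (nm in names(spec)) {
      if (is.null(spec[[nm]][1]) || is.na(spec[[nm]][1])) next
      xyz <- try_atom(model, ch, as.integer(spec[[nm]][1]), spec[[nm]][2])
      if (!is.null(xyz))
        donors[[paste(ch, nm)]] <- xyz
    }
  }
  if (!length(donors))
    stop("engaged_nucleotides: no donor atoms resolvable in the ring")
  dmat <- do.call(rbind, donors)
  acceptors <- c("P", "OP1", "OP2", "O5'", "O3'", "O4'")
  engaged <- integer(0); contacts <- list()
  for (i in seq_len(nrow(res))) {
    hit <- FALSE
    for (at in acceptors) {
      xyz <- try_atom(model, strand, res$resno[i], at)
      if (is.null(xyz)) next
      d <- sqrt(rowSums(sweep(dmat, 2L, xyz)^2))
      j <- which(d <= criteria$engagement_max)
      if (length(j)) {
        hit <- TRUE
        contacts[[length(contacts) + 1L]] <-
          data.frame(nucleotide = res$resno[i], acceptor = at,
                     donor = rownames(dmat)[j[1]], distance = d[j[1]],
                     stringsAsFactors = FALSE)
      }
    }
    if (hit) engaged <- c(engaged, res$resno[i])
  }
  list(count = length(engaged), resnums = engaged,
       donor_contacts = if (length(contacts)) do.call(rbind, contacts)
                        else data.frame())
}

#' @export
print.DuplexRegister <- function(x, ...) {
  cat("DuplexRegister ", x$strand_a, ":", x$strand_b, " - ",
      nrow(x$pair_map), " Watson-Crick pairs",
      sep = "")
  if (length(x$unpaired_a))
    cat("; unpaired on ", x$strand_a, ": ",
        paste(x$unpaired_a, collapse = ","), sep = "")
  if (length(x$unpaired_b))
    cat("; unpaired on ", x$strand_b, ": ",
        paste(x$unpaired_b, collapse = ","), sep = "")
  cat("\n")
  invisible(x)
}
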