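#' Specification for a synthetic two-tier ring
#'
#' Parameterizes a hexameric (or generic n-meric) two-tier ring whose
#' analysis-relevant geometry is programmed exactly: each subunit's
#' inter-tier dihedral equals its `per_subunit_twist` entry, and each
#' interface's two anchor CA-CA distances equal the `interface_atp` /
#' `interface_h2i` entries.  Subunits carry an OB-fold proxy (107 CA
#' pseudo-residues at the OB residue numbers), an AAA+ core proxy (152 CA
#' pseudo-residues at the deposited core numbers) and all anchor residues,
#' so fixtures exercise the same lookup paths as real depositions.
#'
#' @param n_subunits number of subunits (default 6).
#' @param ring_radius subunit-center radius in Angstrom (default 40).
#' @param tier_separation N-tier to C-tier spacing in Angstrom (default 45).
#' @param per_subunit_twist degrees in (-180, 180], one per subunit;
#'   the programmed inter-tier dihedral.
#' @param interface_atp,interface_h2i Angstrom, one per interface (interface
#'   i joins subunit i to subunit i+1).
#' @param seed RNG seed for the deterministic pseudo-residue clouds.
#' @return a `RingSpec` list.
#' @export
ring_spec <- function(n_subunits = 6, ring_radius = 40, tier_separation = 45,
                      per_subunit_twist = rep(0, n_subunits),
                      interface_atp = rep(5.0, n_subunits),
                      interface_h2i = rep(7.0, n_subunits),
                      seed = 1L) {
  if (length(per_subunit_twist) != n_subunits ||
      length(interface_atp) != n_subunits ||
      length(interface_h2i) != n_subunits)
    stop("ring_spec: per-subunit/per-interface lists must have length ",
         n_subunits)
  if (any(per_subunit_twist <= -180 | per_subunit_twist > 180))
    stop("ring_spec: twists must lie in (-180, 180]")
  if (any(interface_atp <= 0) || any(interface_h2i <= 0))
    stop("ring_spec: interface distances must be positive")
  if (any(interface_atp >= tier_separation) ||
      any(interface_h2i >= tier_separation))
    stop("ring_spec: geometrically infeasible interface distance ",
         "(must be smaller than the tier separation)")
  list(n_subunits = as.integer(n_subunits), ring_radius = ring_radius,
       tier_separation = tier_separation,
       per_subunit_twist = per_subunit_twist,
       interface_atp = interface_atp, interface_h2i = interface_h2i,
       seed = as.integer(seed))
}

# anchor residue numbers of the synthetic subunit (deposited archaeal scheme)
SYN_OB_RANGES <- list(c(105, 130), c(185, 265))
SYN_CORE_RANGES <- list(c(1319, 1361), c(1729, 1837))
SYN_ANCHORS <- list(ob_anchor = 201L, aaa_anchor = 1755L,
                    walkerA_pro = 1330L, argfinger_minus4 = 1824L,
                    h2i_leu = 1361L, ps1b_lys = 1785L,
                    h2i_hydroxyl = 1357L, h2i_amide = 1732L,
                    ps1b_amide = 1786L)
SYN_RESID <- c("201" = "PRO", "1330" = "PRO", "1361" = "LEU",
               "1755" = "TYR", "1785" = "LYS", "1824" = "THR",
               "1357" = "SER", "1732" = "ALA", "1786" = "ALA")

#' Generate a synthetic two-tier ring model
#'
#' Builds the ring described by a [ring_spec()].  Construction guarantees,
#' to machine precision: pooled OB centroid on the ring axis at z = 0;
#' pooled core centroid on the axis at z = tier_separation; each subunit's
#' four-point inter-tier dihedral exactly equal to its programmed twist
#' (the C-tier dihedral anchor is placed at azimuth theta_i + twist_i); and
#' each interface's two anchor distances exactly equal to the programmed
#' values (partner anchors are offset purely along z at a shared azimuth).
#' Non-anchor pseudo-residues form a seeded deterministic cloud whose
#' positions are adjusted so every subunit's tier centroid sits exactly at
#' its center; with uniform twists and distances all subunits are exact
#' rigid copies of one another.
#'
#' @param spec a [ring_spec()].
#' @param id model identifier.
#' @return list with `model` (a `StructureModel`, chains A, B, ...) and
#'   `truth` (the programmed ground-truth values).
#' @export
make_ring <- function(spec, id = "synthetic_ring") {
  n <- spec$n_subunits
  R <- spec$ring_radius; ts <- spec$tier_separation
  chains <- LETTERS[seq_len(n)]
  theta <- (seq_len(n) - 1) * 2 * pi / n
  phi <- theta + pi / n            # interface azimuths
  ob_res <- unlist(lapply(SYN_OB_RANGES, function(r) seq(r[1], r[2])))
  core_res <- unlist(lapply(SYN_CORE_RANGES, function(r) seq(r[1], r[2])))
  with_seed(spec$seed, {
    ob_cloud <- cloud_points(length(ob_res) - 1L, 6)       # all but anchor 201
    core_cloud <- cloud_points(length(core_res) - 5L, 6)   # minus 5 anchors
  })
  rows <- list()
  add <- function(chain, resno, elety, xyz) {
    rows[[length(rows) + 1L]] <<- data.frame(
      chain = chain, resno = as.integer(resno),
      resid = unname(ifelse(as.character(resno) %in% names(SYN_RESID),
                            SYN_RESID[as.character(resno)], "ALA")),
      elety = elety, x = xyz[1], y = xyz[2], z = xyz[3], het = FALSE,
      stringsAsFactors = FALSE)
  }
  rotz <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0,
                               0, 0, 1), 3, 3)
  for (i in seq_len(n)) {
    ch <- chains[i]
    cN <- c(R * cos(theta[i]), R * sin(theta[i]), 0)
    cC <- c(R * cos(theta[i]), R * sin(theta[i]), ts)
    tw <- spec$per_subunit_twist[i] * pi / 180
    # --- N tier: OB anchor at azimuth theta_i exactly
    ob_anchor <- c((R + 8) * cos(theta[i]), (R + 8) * sin(theta[i]), -4)
    cl <- ob_cloud %*% t(rotz(theta[i]))
    cl <- sweep(cl, 2L, cN, "+")
    delta <- (length(ob_res) * cN - (colSums(cl) + ob_anchor)) /
      nrow(cl)
    cl <- sweep(cl, 2L, delta, "+")
    ob_rest <- setdiff(ob_res, SYN_ANCHORS$ob_anchor)
    for (k in seq_along(ob_rest)) add(ch, ob_rest[k], "CA", cl[k, ])
    add(ch, SYN_ANCHORS$ob_anchor, "CA", ob_anchor)
    # --- C tier constrained anchors
    ip <- ((i - 2) %% n) + 1L      # interface arriving at this subunit
    aaa_anchor <- c((R + 8) * cos(theta[i] + tw),
                    (R + 8) * sin(theta[i] + tw), ts + 4)
    walkerA <- c(R * cos(phi[i]), R * sin(phi[i]), ts + 6)
    argf <- c(R * cos(phi[ip]), R * sin(phi[ip]),
              ts + 6 - spec$interface_atp[ip])
    h2i <- c((R - 5) * cos(phi[i]), (R - 5) * sin(phi[i]), ts + 2)
    ps1b <- c((R - 5) * cos(phi[ip]), (R - 5) * sin(phi[ip]),
              ts + 2 - spec$interface_h2i[ip])
    anchors_c <- rbind(aaa_anchor, walkerA, argf, h2i, ps1b)
    cl <- core_cloud %*% t(rotz(theta[i]))
    cl <- sweep(cl, 2L, cC, "+")
    delta <- (length(core_res) * cC - (colSums(cl) + colSums(anchors_c))) /
      nrow(cl)
    cl <- sweep(cl, 2L, delta, "+")
    core_rest <- setdiff(core_res,
                         unlist(SYN_ANCHORS[c("aaa_anchor", "walkerA_pro",
                                              "argfinger_minus4", "h2i_leu",
                                              "ps1b_lys")]))
    for (k in seq_along(core_rest)) add(ch, core_rest[k], "CA", cl[k, ])
    add(ch, SYN_ANCHORS$aaa_anchor, "CA", aaa_anchor)
    add(ch, SYN_ANCHORS$walkerA_pro, "CA", walkerA)
    add(ch, SYN_ANCHORS$argfinger_minus4, "CA", argf)
    add(ch, SYN_ANCHORS$h2i_leu, "CA", h2i)
    add(ch, SYN_ANCHORS$ps1b_lys, "CA", ps1b)
    # donor atoms for DNA-engagement analyses, radially offset from their CA
    donor_of <- function(resno, elety) {
      ca <- if (resno == SYN_ANCHORS$ps1b_lys) ps1b
            else cl[match(resno, core_rest), ]
      az <- atan2(ca[2], ca[1])
      add(ch, resno, elety, ca + c(1.5 * cos(az), 1.5 * sin(az), 0))
    }
    donor_of(SYN_ANCHORS$ps1b_lys, "NZ")
    donor_of(SYN_ANCHORS$ps1b_amide, "N")
    donor_of(SYN_ANCHORS$h2i_hydroxyl, "OG")
    donor_of(SYN_ANCHORS$h2i_amide, "N")
  }
  atoms <- do.call(rbind, rows)
  model <- new_structure_model(id, atoms, "cif")
  truth <- list(spec = spec,
                dihedral = stats::setNames(spec$per_subunit_twist, chains),
                interface_atp = spec$interface_atp,
                interface_h2i = spec$interface_h2i,
                ring = ring_map(chains, rep("archaeal", n)))
  list(model = model, truth = truth)
}

cloud_points <- function(n, radius) {
  m <- matrix(stats::runif(3 * n, -radius, radius), ncol = 3)
  sweep(m, 2L, colMeans(m))
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  eval.parent(substitute(code))
}

#' Specification for an idealized B-DNA duplex
#'
#' @param sequence strand-a sequence, 5' to 3', over A/C/G/T.
#' @param rise helical rise per base pair in Angstrom (default 3.38).
#' @param twist_per_bp helical twist per base pair in degrees (default 36).
#' @param melted_5prime number of 5'-terminal strand-a nucleotides whose
#'   complements are omitted from strand b (melted; default 0).
#' @return a `DnaSpec` list.
#' @export
dna_spec <- function(sequence, rise = 3.38, twist_per_bp = 36.0,
                     melted_5prime = 0L) {
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop("dna_spec: empty sequence")
  bases <- strsplit(sequence, "")[[1]]
  if (!all(bases %in% c("A", "C", "G", "T")))
    stop("dna_spec: sequence must be over A/C/G/T")
  if (melted_5prime < 0 || melted_5prime > length(bases))
    stop("dna_spec: melted_5prime must be in 0..length(sequence)")
  list(sequence = bases, rise = rise, twist_per_bp = twist_per_bp,
       melted_5prime = as.integer(melted_5prime))
}

#' Generate an idealized B-DNA duplex model
#'
#' Ideal helix with the given rise and twist; every nucleotide carries P,
#' C1', N1 and N3 atoms with canonical Watson-Crick geometry across the
#' pair (C1'-C1' 10.4 A, purine-N1 to pyrimidine-N3 2.9 A), so the default
#' pairing criteria detect the full register without tuning.  Strand b is
#' the antiparallel complement; the partners of the first `melted_5prime`
#' strand-a nucleotides (strand b's 3'-terminal nucleotides) are omitted,
#' emulating melted, disordered complements.
#'
#' @param spec a [dna_spec()].
#' @param chain_a,chain_b chain identifiers (defaults "X", "Y").
#' @param id model identifier.
#' @return a `StructureModel`.
#' @export
make_bdna <- function(spec, chain_a = "X", chain_b = "Y", id = "synthetic_dna") {
  n <- length(spec$sequence)
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  code <- c(A = "DA", C = "DC", G = "DG", T = "DT")
  rows <- list()
  add <- function(chain, resno, resid, elety, xyz) {
    rows[[length(rows) + 1L]] <- data.frame(
      chain = chain, resno = as.integer(resno), resid = resid,
      elety = elety, x = xyz[1], y = xyz[2], z = xyz[3], het = FALSE,
      stringsAsFactors = FALSE)
    assign("rows", rows, envir = parent.frame())
  }
  emit_nt <- function(chain, resno, base, u, z, side, p_az) {
    resid <- code[[base]]
    purine <- base %in% c("A", "G")
    wc <- side * 1.45 * u + c(0, 0, z)
    other <- side * 3.5 * u + c(0, 0, z + 0.5)
    rows[[length(rows) + 1L]] <<- data.frame(
      chain = chain, resno = as.integer(resno), resid = resid,
      elety = c("P", "C1'", if (purine) c("N1", "N3") else c("N3", "N1")),
      x = c(8.9 * cos(p_az), side * 5.2 * u[1], wc[1], other[1]),
      y = c(8.9 * sin(p_az), side * 5.2 * u[2], wc[2], other[2]),
      z = c(z, z, wc[3], other[3]), het = FALSE, stringsAsFactors = FALSE)
  }
  for (j in seq_len(n)) {
    alpha <- (j - 1) * spec$twist_per_bp * pi / 180
    z <- (j - 1) * spec$rise
    u <- c(cos(alpha), sin(alpha), 0)
    emit_nt(chain_a, j, spec$sequence[j], u, z, +1, alpha + 50 * pi / 180)
    k <- n + 1L - j
    if (k <= n - spec$melted_5prime)
      emit_nt(chain_b, k, comp[[spec$sequence[j]]], u, z, -1,
              alpha + pi - 50 * pi / 180)
  }
  atoms <- do.call(rbind, rows)
  new_structure_model(id, atoms, "cif")
}

#' Combine two models into one
#'
#' @param a,b `StructureModel`s with disjoint chain identifiers.
#' @param id identifier for the combined model.
#' @return a `StructureModel`.
#' @export
combine_models <- function(a, b, id = paste(a$id, b$id, sep = "+")) {
  shared <- intersect(unique(a$atoms$chain), unique(b$atoms$chain))
  if (length(shared))
    stop("combine_models: chain identifiers clash: ",
         paste(shared, collapse = ", "))
  new_structure_model(id, rbind(a$atoms, b$atoms), a$source_format)
}

#' Place hairpin donor atoms at programmed distances from DNA phosphates
#'
#' Repositions the named donor atom of each listed subunit so it sits at
#' exactly `distance` from the phosphorus of the given tracked-strand
#' nucleotide (along the line from the phosphate to the donor's current
#' position).  Used to build engagement ground truth.
#'
#' @param model combined ring+DNA `StructureModel`.
#' @param anchors an `AnchorSet`.
#' @param assignments data.frame with columns `chain` (subunit), `donor`
#'   ("ps1b_lys", "ps1b_amide", "h2i_hydroxyl" or "h2i_amide"), `dna_chain`,
#'   `dna_resno`.
#' @param subunit anchor-set subunit label for donor residue lookup.
#' @param distance Angstrom (default 3.0).
#' @return the modified `StructureModel`.
#' @export
engage_donors <- function(model, anchors, assignments,
                          subunit = names(anchors$subunits)[1],
                          distance = 3.0) {
  su <- subunit_anchors(anchors, subunit)
  donor_atom <- c(ps1b_lys = "NZ", ps1b_amide = "N",
                  h2i_hydroxyl = "OG", h2i_amide = "N")
  for (r in seq_len(nrow(assignments))) {
    d <- assignments$donor[r]
    resno <- su[[d]]
    elety <- donor_atom[[d]]
    p <- get_atom_xyz(model, assignments$dna_chain[r],
                      assignments$dna_resno[r], "P")
    idx <- which(model$atoms$chain == assignments$chain[r] &
                   model$atoms$resno == resno &
                   model$atoms$elety == elety)
    if (length(idx) != 1L)
      stop("engage_donors: donor ", d, " not found on chain ",
           assignments$chain[r])
    cur <- as.numeric(model$atoms[idx, c("x", "y", "z")])
    dir <- cur - p
    nrm <- sqrt(sum(dir^2))
    if (nrm < 1e-9) dir <- c(1, 0, 0) else dir <- dir / nrm
    model$atoms[idx, c("x", "y", "z")] <- p + distance * dir
  }
  model
}

#' Apply a rigid motion to a whole model
#'
#' @param model a `StructureModel`.
#' @param rotation 3 x 3 rotation matrix (default identity).
#' @param translation length-3 vector (default zero).
#' @return the transformed `StructureModel`.
#' @export
transform_model <- function(model, rotation = diag(3),
                            translation = c(0, 0, 0)) {
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  xyz <- sweep(xyz %*% t(rotation), 2L, translation, "+")
  model$atoms[, c("x", "y", "z")] <- xyz
  model
}
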