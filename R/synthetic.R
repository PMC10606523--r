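## Synthetic fixture generators with analytic or constructed ground truth.
## Pseudo-trajectories use unconstrained Gaussian jitter (not physical
## dynamics) -- sufficient for exercising the ensemble statistics.

.AA13 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
           E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
           M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
           Y = "TYR", V = "VAL")

#' Single-charge Born sphere with analytic transfer energy
#'
#' One atom of radius \code{a} carrying charge \code{q}, plus the closed-form
#' transfer energy of the Born ion between two exterior permittivities:
#' \code{(332.0636 / (2 a)) (1/epsTo - 1/epsFrom)} kcal/mol.
#'
#' @param q charge, e
#' @param a sphere radius, Angstrom
#' @param epsFrom,epsTo exterior permittivities of the two environments
#' @param center atom position
#' @return list(structure, analytic) -- analytic in kcal/mol
#' @export
makeBornSphere <- function(q = 1, a = 2, epsFrom = 81, epsTo = 4,
                           center = c(0, 0, 0)) {
  stopifnot(a > 0)
  if (epsFrom < 1 || epsTo < 1) stop("permittivities must be >= 1")
  atoms <- data.frame(serial = 1L, name = "Q", element = "O",
                      resname = "ION", resno = 1L, chain = "A",
                      x = center[1], y = center[2], z = center[3],
                      charge = q, radius = a, stringsAsFactors = FALSE)
  list(structure = .newStructure(atoms),
       analytic = q^2 * .COULOMB / (2 * a) * (1 / epsTo - 1 / epsFrom))
}

#' Two point charges with analytic Coulomb interaction
#'
#' @param q1,q2 charges, e
#' @param r separation, Angstrom (error below the 2 A contact distance)
#' @param eps uniform permittivity for the analytic value
#' @param center midpoint of the pair
#' @return list(structure, analytic = 332.0636 q1 q2 / (eps r) kcal/mol)
#' @export
makeChargePair <- function(q1, q2, r, eps = 20, center = c(0, 0, 0)) {
  stopifnot(r > 0)
  if (r < 2) stop("separation ", r, " A is below the 2 A contact distance")
  atoms <- data.frame(serial = 1:2, name = c("Q1", "Q2"),
                      element = c("O", "O"), resname = c("ION", "ION"),
                      resno = 1:2, chain = c("A", "A"),
                      x = center[1] + c(-r / 2, r / 2),
                      y = center[2], z = center[3],
                      charge = c(q1, q2), radius = c(1.0, 1.0),
                      stringsAsFactors = FALSE)
  list(structure = .newStructure(atoms),
       analytic = .COULOMB * q1 * q2 / (eps * r))
}

## side-chain atom offsets in the local (radial, tangential, axial) frame;
## default protonation: acids deprotonated, bases protonated
.SIDECHAINS <- list(
  ALA = list(CB = c(1.5, 0, 0.3)),
  GLY = list(),
  PRO = list(CB = c(1.5, 0, 0.3), CG = c(2.3, 1.0, 0.5),
             CD = c(1.6, 1.9, 0.1)),
  SER = list(CB = c(1.5, 0, 0.3), OG = c(2.8, 0.3, 0.8),
             HG = c(3.5, 0.5, 1.0)),
  CYS = list(CB = c(1.5, 0, 0.3), SG = c(3.0, 0.3, 0.9),
             HG = c(3.9, 0.5, 1.2)),
  ASP = list(CB = c(1.5, 0, 0.3), CG = c(2.8, 0.3, 0.8),
             OD1 = c(3.5, 1.3, 0.9), OD2 = c(3.3, -0.8, 1.2)),
  GLU = list(CB = c(1.5, 0, 0.3), CG = c(2.7, 0.4, 0.8),
             CD = c(4.0, 0.2, 1.2), OE1 = c(4.7, 1.2, 1.3),
             OE2 = c(4.5, -0.9, 1.6)),
  LYS = list(CB = c(1.5, 0, 0.3), CG = c(2.7, 0.4, 0.7),
             CD = c(3.9, 0.1, 1.2), CE = c(5.1, 0.5, 1.6),
             NZ = c(6.2, 0.2, 2.0), HZ1 = c(6.8, 0.9, 2.2),
             HZ2 = c(6.6, -0.5, 1.7), HZ3 = c(6.3, 0.1, 2.9)),
  ARG = list(CB = c(1.5, 0, 0.3), CG = c(2.7, 0.4, 0.7),
             CD = c(3.9, 0.1, 1.2), NE = c(5.0, 0.6, 1.6),
             HE = c(5.0, 1.6, 1.6), CZ = c(6.2, 0.2, 1.9),
             NH1 = c(7.2, 0.9, 2.2), HH11 = c(7.1, 1.9, 2.2),
             HH12 = c(8.1, 0.5, 2.4), NH2 = c(6.4, -1.1, 2.0),
             HH21 = c(5.7, -1.7, 1.8), HH22 = c(7.2, -1.5, 2.2)),
  TYR = list(CB = c(1.5, 0, 0.3), CG = c(2.9, 0.2, 0.7),
             CD1 = c(3.6, 1.2, 1.0), CD2 = c(3.6, -0.9, 0.9),
             CE1 = c(5.0, 1.3, 1.3), CE2 = c(5.0, -0.8, 1.2),
             CZ = c(5.7, 0.3, 1.5), OH = c(7.0, 0.4, 1.8),
             HH = c(7.5, 1.2, 1.9)),
  HIS = list(CB = c(1.5, 0, 0.3), CG = c(2.8, 0.2, 0.7),
             ND1 = c(3.5, 1.2, 1.0), HD1 = c(3.2, 2.1, 1.0),
             CD2 = c(3.7, -0.9, 1.0), CE1 = c(4.8, 1.0, 1.3),
             NE2 = c(4.9, -0.4, 1.3), HE2 = c(5.7, -0.9, 1.5))
)

.sideChainOffsets <- function(resname) {
  sc <- .SIDECHAINS[[resname]]
  if (is.null(sc)) sc <- .SIDECHAINS[["ALA"]]
  sc
}

#' Ideal alpha-helix with chosen titratable residues, oriented along z
#'
#' Rise 1.5 A per residue, 100 degree twist, CA radius 2.3 A; side chains
#' placed on canonical radial offsets. Poly-Ala except at the requested
#' placements. With a \linkS4class{MembraneSlab} given, the helix is centred
#' so that its axial midpoint sits at the slab's core midplane (plus
#' \code{zShift}).
#'
#' @param placements data.frame(type, position) or list of c(type, position);
#'   empty for poly-Ala
#' @param nRes helix length in residues
#' @param slab optional \linkS4class{MembraneSlab} used for centring
#' @param sequence optional 1-letter sequence overriding nRes/placements
#' @param zShift axial offset, Angstrom
#' @param xy lateral position of the helix axis
#' @param phase initial twist angle in degrees (rotates all side chains)
#' @param chain chain id
#' @param table parameter table used to assign charges
#' @param seed unused (geometry is deterministic); kept for interface parity
#' @return a parameterized \linkS4class{ParameterizedStructure}
#' @export
makeHelixInSlab <- function(placements = NULL, nRes = 20, slab = NULL,
                            sequence = NULL, zShift = 0, xy = c(0, 0),
                            phase = 0, chain = "A",
                            table = loadParameterTable(), seed = 1) {
  if (!is.null(sequence)) {
    letters1 <- strsplit(toupper(sequence), "")[[1]]
    types <- unname(.AA13[letters1])
    if (any(is.na(types)))
      stop("unknown residue letters: ",
           paste(unique(letters1[is.na(types)]), collapse = ", "))
    nRes <- length(types)
  } else {
    types <- rep("ALA", nRes)
    if (!is.null(placements)) {
      if (is.data.frame(placements))
        placements <- lapply(seq_len(nrow(placements)), function(i)
          list(type = placements$type[i], position = placements$position[i]))
      posSeen <- integer(0)
      for (p in placements) {
        pp <- as.integer(p[["position"]])
        if (pp < 1 || pp > nRes)
          stop("placement position ", pp, " outside helix of ", nRes,
               " residues")
        if (pp %in% posSeen) stop("clashing placements at position ", pp)
        posSeen <- c(posSeen, pp)
        types[pp] <- toupper(p[["type"]])
      }
    }
  }
  rise <- 1.5; twist <- 100 * pi / 180; caRadius <- 2.3
  z0 <- -(nRes - 1) * rise / 2 + zShift
  if (!is.null(slab)) z0 <- z0 + (slab@coreZmin + slab@coreZmax) / 2
  rows <- list()
  serial <- 0L
  addAtom <- function(name, p, resname, resno) {
    serial <<- serial + 1L
    rows[[length(rows) + 1]] <<- data.frame(
      serial = serial, name = name, element = .elementFromName(name),
      resname = resname, resno = resno, chain = chain,
      x = p[1], y = p[2], z = p[3], charge = NA_real_, radius = NA_real_,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(nRes)) {
    th <- (i - 1) * twist + phase * pi / 180
    u <- c(cos(th), sin(th), 0)
    v <- c(-sin(th), cos(th), 0)
    w <- c(0, 0, 1)
    ca <- c(xy[1], xy[2], 0) + caRadius * u + c(0, 0, z0 + (i - 1) * rise)
    local_ <- function(d) ca + d[1] * u + d[2] * v + d[3] * w
    resname <- types[i]
    addAtom("N", local_(c(-0.4, -1.2, -0.5)), resname, i)
    if (resname != "PRO") addAtom("HN", local_(c(-1.0, -1.9, -0.7)),
                                  resname, i)
    addAtom("CA", ca, resname, i)
    addAtom("C", local_(c(-0.3, 1.2, 0.6)), resname, i)
    addAtom("O", local_(c(-1.0, 1.9, 0.4)), resname, i)
    for (nm in names(.sideChainOffsets(resname)))
      addAtom(nm, local_(.sideChainOffsets(resname)[[nm]]), resname, i)
  }
  atoms <- do.call(rbind, rows)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  dmin <- min(stats::dist(xyz))
  if (dmin < 0.5)
    stop("clashing placements: minimum interatomic distance ",
         round(dmin, 3), " A")
  assignParse(.newStructure(atoms), table)
}

#' Combine structures into one multi-chain system
#'
#' @param structures list of \linkS4class{ParameterizedStructure}
#' @param chains chain ids to assign (defaults A, B, ...)
#' @return one \linkS4class{ParameterizedStructure}
#' @export
mergeStructures <- function(structures, chains = LETTERS[seq_along(structures)]) {
  parts <- lapply(seq_along(structures), function(i) {
    a <- atoms(structures[[i]])
    a$chain <- chains[i]
    a
  })
  a <- do.call(rbind, parts)
  a$serial <- seq_len(nrow(a))
  .newStructure(a)
}

#' Gaussian-jitter pseudo-trajectory
#'
#' Adds iid Gaussian displacements (sd \code{jitterSigma} per coordinate) to
#' every atom of the base structure, independently per frame. Bonds are not
#' preserved; the frames emulate positional fluctuation for electrostatic
#' ensemble statistics, not dynamics. Deterministic for a given seed.
#'
#' @param base a \linkS4class{ParameterizedStructure}
#' @param jitterSigma displacement sd per coordinate, Angstrom (>= 0)
#' @param nFrames number of frames (>= 1)
#' @param seed RNG seed
#' @param file optional path to also write a multi-model PDB
#' @return list of \linkS4class{ParameterizedStructure} with frameId 1..n
#' @export
makePseudoTrajectory <- function(base, jitterSigma, nFrames, seed = 1,
                                 file = NULL) {
  if (jitterSigma < 0) stop("jitterSigma must be >= 0")
  stopifnot(nFrames >= 1)
  set.seed(seed)
  a0 <- atoms(base)
  frames <- lapply(seq_len(nFrames), function(f) {
    a <- a0
    a$x <- a$x + stats::rnorm(nrow(a), 0, jitterSigma)
    a$y <- a$y + stats::rnorm(nrow(a), 0, jitterSigma)
    a$z <- a$z + stats::rnorm(nrow(a), 0, jitterSigma)
    .newStructure(a, frameId = f)
  })
  if (!is.null(file)) writePdb(frames, file)
  frames
}

## fixed codon per amino acid (none are stop codons)
.CODON <- c(A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT",
            Q = "CAA", E = "GAA", G = "GGT", H = "CAT", I = "ATT",
            L = "CTG", K = "AAA", M = "ATG", F = "TTT", P = "CCT",
            S = "TCT", T = "ACT", W = "TGG", Y = "TAT", V = "GTT")

.composeSegment <- function(counts, len, fill, hasM = FALSE) {
  counts <- counts[counts > 0]
  need <- sum(counts) + as.integer(hasM)
  if (need > len)
    stop("composition (", need, " residues) exceeds segment length ", len)
  aa <- c(rep(names(counts), counts),
          rep_len(fill, len - need))
  aa <- sample(aa)
  if (hasM) aa <- c("M", aa)
  aa
}

#' Toy coding sequence with a known residue composition
#'
#' Builds an ATG-initiated, stop-terminated CDS whose translation carries
#' exactly the requested ionogenic counts in the mature part (and optionally
#' a leader/transit peptide with its own composition). Non-requested
#' positions are filled with non-ionogenic residues. Deterministic per seed.
#'
#' @param counts named integer vector over a subset of
#'   {R, K, Y, E, D, H, C} for the mature segment
#' @param matureLength mature segment length, residues
#' @param leaderCounts optional composition of the leader segment
#' @param leaderLength leader length in residues (0 = no leader; the leader
#'   includes the initiator Met)
#' @param seed RNG seed
#' @param id sequence id
#' @return list(cds = \linkS4class{CodingSequence}, groundTruth = list with
#'   the requested censuses and segment lengths)
#' @export
makeToyCds <- function(counts = c(R = 0, K = 0, Y = 0, E = 0, D = 0),
                       matureLength = 50, leaderCounts = NULL,
                       leaderLength = 0, seed = 1, id = "toy_cds") {
  set.seed(seed)
  fill <- c("A", "L", "G", "F", "S", "T", "V", "I", "P", "M", "Q", "N", "W")
  if (leaderLength > 0) {
    leader <- .composeSegment(if (is.null(leaderCounts)) integer(0)
                              else leaderCounts,
                              leaderLength, fill, hasM = TRUE)
    mature <- .composeSegment(counts, matureLength, fill, hasM = FALSE)
    aa <- c(leader, mature)
  } else {
    aa <- .composeSegment(counts, matureLength, fill, hasM = TRUE)
  }
  nt <- paste0(paste(.CODON[aa], collapse = ""), "TAA")
  list(cds = codingSequence(nt, id = id),
       groundTruth = list(counts = as.list(counts),
                          leaderCounts = as.list(if (is.null(leaderCounts))
                            integer(0) else leaderCounts),
                          matureLength = length(aa) -
                            if (leaderLength > 0) leaderLength else 0,
                          leaderLength = leaderLength,
                          cdsLength = nchar(nt)))
}

#' Synthetic PsbS-like precursor CDS
#'
#' A synthetic stand-in for the algal PsbS precursor transcript: 756 nt CDS
#' encoding a 251-residue precursor whose 41-residue transit peptide carries
#' 5 Arg, 1 Lys and 1 His, and whose 210-residue mature part carries exactly
#' 9 Arg, 12 Lys, 4 Tyr, 10 Glu and 7 Asp (42 ionogenic residues, no His or
#' Cys). The composition is the generator's input; every census in the
#' package is computed from the sequence.
#'
#' @param seed RNG seed controlling residue placement
#' @return as \code{\link{makeToyCds}}
#' @export
syntheticPsbsCds <- function(seed = 1) {
  makeToyCds(counts = c(R = 9, K = 12, Y = 4, E = 10, D = 7),
             matureLength = 210,
             leaderCounts = c(R = 5, K = 1, H = 1), leaderLength = 41,
             seed = seed, id = "synthetic_psbs_like")
}
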