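## Structure input/output and electrostatic parameterization.

.SOLVENT_RES <- c("HOH", "WAT", "TIP", "TIP3", "SOL", "SPC")

.newStructure <- function(atoms, frameId = 0L) {
  rownames(atoms) <- NULL
  new("ParameterizedStructure", atoms = atoms,
      chains = unique(atoms$chain), frameId = as.integer(frameId))
}

.elementFromName <- function(name) {
  ## first alphabetic character of the atom name; digits (as in HH11) skipped
  el <- sub("^[0-9]*", "", name)
  toupper(substr(el, 1, 1))
}

.atomsFromBio3d <- function(at) {
  chain <- ifelse(is.na(at$chain) | at$chain == "", "A", at$chain)
  el <- at$elesy
  el[is.na(el) | el == ""] <- .elementFromName(at$elety[is.na(el) | el == ""])
  data.frame(serial = at$eleno, name = at$elety, element = el,
             resname = at$resid, resno = at$resno, chain = chain,
             x = at$x, y = at$y, z = at$z,
             charge = NA_real_, radius = NA_real_,
             occupancy = if ("o" %in% names(at)) at$o else NA_real_,
             alt = if ("alt" %in% names(at)) at$alt else NA_character_,
             stringsAsFactors = FALSE)
}

.checkRecords <- function(lines) {
  rec <- grep("^(ATOM|HETATM)", lines)
  for (i in rec) {
    ln <- lines[i]
    flds <- strsplit(trimws(ln), "\\s+")[[1]]
    if (nchar(ln) < 54 && length(flds) < 9)
      stop("malformed ATOM/HETATM record at line ", i, ": ", ln)
  }
  invisible(length(rec))
}

.dropAltLoc <- function(atoms) {
  if (!"alt" %in% names(atoms) || all(is.na(atoms$alt) | atoms$alt == ""))
    return(atoms)
  key <- paste(atoms$chain, atoms$resno, atoms$name, sep = "|")
  keep <- rep(TRUE, nrow(atoms))
  for (k in unique(key[duplicated(key)])) {
    idx <- which(key == k)
    occ <- atoms$occupancy[idx]
    best <- if (all(is.na(occ))) idx[1] else idx[which.max(occ)]
    keep[setdiff(idx, best)] <- FALSE
  }
  atoms[keep, , drop = FALSE]
}

#' Read a structure from PDB or PQR
#'
#' Parses ATOM/HETATM records, preserving file order and author residue
#' numbering. PQR charge and radius columns are carried through; PDB input
#' leaves charges and radii unset until \code{\link{assignParse}}. Alternate
#' locations are resolved to the highest-occupancy copy.
#'
#' @param file path to a PDB or PQR file (or a character vector of lines via
#'   \code{text})
#' @param format "auto" (by extension), "pdb" or "pqr"
#' @param stripSolvent drop water records
#' @param text optional character vector of raw record lines instead of a file
#' @return a \linkS4class{ParameterizedStructure}
#' @examples
#' pqr <- c("ATOM      1  O   SPH A   1       0.000   0.000   0.000 -0.5500 1.5000")
#' s <- readStructure(text = pqr, format = "pqr")
#' atoms(s)$charge
#' @export
readStructure <- function(file, format = c("auto", "pdb", "pqr"),
                          stripSolvent = FALSE, text = NULL) {
  format <- match.arg(format)
  if (!is.null(text)) {
    file <- tempfile(fileext = if (format == "pqr") ".pqr" else ".pdb")
    on.exit(unlink(file))
    writeLines(text, file)
  }
  if (format == "auto")
    format <- if (grepl("\\.pqr$", file, ignore.case = TRUE)) "pqr" else "pdb"
  lines <- readLines(file, warn = FALSE)
  .checkRecords(lines)
  obj <- tryCatch(
    if (format == "pqr") bio3d::read.pqr(file)
    else suppressWarnings(bio3d::read.pdb(file)),
    error = function(e) stop("failed to parse ", format, " input: ",
                             conditionMessage(e)))
  atoms <- .atomsFromBio3d(obj$atom)
  if (format == "pqr") {
    atoms$charge <- obj$atom$o
    atoms$radius <- obj$atom$b
  }
  if (stripSolvent) atoms <- atoms[!atoms$resname %in% .SOLVENT_RES, ,
                                   drop = FALSE]
  atoms <- .dropAltLoc(atoms)
  key <- paste(atoms$chain, atoms$resno, atoms$name, sep = "|")
  if (anyDuplicated(key))
    stop("duplicate (chain, residue, atom) records: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  atoms$occupancy <- NULL
  atoms$alt <- NULL
  .newStructure(atoms)
}

#' Read a multi-model PDB as a list of frames
#'
#' @param file multi-model PDB path
#' @param stripSolvent drop water records
#' @return list of \linkS4class{ParameterizedStructure}, frameId 1..n
#' @export
readFrames <- function(file, stripSolvent = FALSE) {
  lines <- readLines(file, warn = FALSE)
  starts <- grep("^MODEL", lines)
  if (!length(starts)) return(list(readStructure(file,
                                                 stripSolvent = stripSolvent)))
  ends <- grep("^ENDMDL", lines)
  if (length(ends) != length(starts))
    stop("unbalanced MODEL/ENDMDL records")
  lapply(seq_along(starts), function(f) {
    s <- readStructure(text = lines[(starts[f] + 1):(ends[f] - 1)],
                       format = "pdb", stripSolvent = stripSolvent)
    s@frameId <- f
    s
  })
}

#' Write a structure as PQR
#'
#' Whitespace-delimited PQR (charge then radius after the coordinates).
#'
#' @param structure a \linkS4class{ParameterizedStructure} with charges and
#'   radii assigned
#' @param file output path
#' @export
writePqr <- function(structure, file) {
  a <- atoms(structure)
  if (any(is.na(a$charge)) || any(is.na(a$radius)))
    stop("structure has unset charges or radii; run assignParse() first")
  lines <- sprintf(
    "ATOM  %5d %-4s %-4s%s%4d    %8.3f%8.3f%8.3f %7.4f %6.4f",
    a$serial %% 100000, a$name, a$resname, substr(a$chain, 1, 1), a$resno,
    a$x, a$y, a$z, a$charge, a$radius)
  writeLines(c(lines, "END"), file)
  invisible(file)
}

#' Write one or more frames as a (multi-model) PDB
#'
#' @param frames a ParameterizedStructure or list of them
#' @param file output path
#' @export
writePdb <- function(frames, file) {
  if (is(frames, "ParameterizedStructure")) frames <- list(frames)
  out <- character(0)
  for (f in seq_along(frames)) {
    a <- atoms(frames[[f]])
    nm <- ifelse(nchar(a$name) < 4, paste0(" ", a$name), a$name)
    recs <- sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
                    a$serial %% 100000, substr(nm, 1, 4), a$resname,
                    substr(a$chain, 1, 1), a$resno, a$x, a$y, a$z, 1.0, 0.0)
    out <- c(out,
             if (length(frames) > 1) sprintf("MODEL %8d", f),
             recs,
             if (length(frames) > 1) "ENDMDL")
  }
  writeLines(c(out, "END"), file)
  invisible(file)
}

## ---------------------------------------------------------------------------
## Parameter assignment
## ---------------------------------------------------------------------------

#' Load a charge/radius parameter table
#'
#' @param file YAML parameter table; default is the set shipped with the
#'   package
#' @return parsed table (list) with components radii, backbone, residues,
#'   titratable
#' @export
loadParameterTable <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "parse_style_params.yaml",
                        package = "ContinuumPKa")
  tab <- yaml::read_yaml(file)
  stopifnot(all(c("radii", "backbone", "residues", "titratable") %in%
                  names(tab)))
  tab
}

.variantCharges <- function(tab, resname, state) {
  t <- tab$titratable[[resname]]
  if (!is.null(t)) {
    ch <- t[[state]]
    list(charges = unlist(ch), parents = unlist(t$parents))
  } else {
    r <- tab$residues[[resname]]
    if (is.null(r)) return(NULL)
    list(charges = unlist(r$charges),
         parents = if (is.null(r$parents)) character(0) else unlist(r$parents))
  }
}

.defaultState <- function(tab, resname) {
  cls <- tab$titratable[[resname]]$class
  if (identical(cls, "acid")) "deprotonated" else "protonated"
}

#' Assign partial charges and radii
#'
#' Looks every atom up in the parameter table (backbone map first, then the
#' residue's side-chain map), assigns Pauling van der Waals radii by element,
#' and verifies that every residue's net charge equals its formal charge to
#' 1e-6 e. For titratable residues the protonation variant is selected by the
#' hydrogens present in the coordinates when unambiguous, otherwise acids are
#' built deprotonated and bases protonated. Charges of table hydrogens absent
#' from the coordinates are collapsed onto their parent heavy atoms, so the
#' per-residue sums hold for heavy-atom-only input too.
#'
#' @param structure a \linkS4class{ParameterizedStructure}
#' @param table parameter table from \code{\link{loadParameterTable}}
#' @return the structure with charge and radius columns filled
#' @export
assignParse <- function(structure, table = loadParameterTable()) {
  a <- atoms(structure)
  a$charge <- 0
  a$radius <- NA_real_
  rad <- unlist(table$radii)
  a$radius <- unname(rad[a$element])
  if (any(is.na(a$radius))) {
    bad <- unique(a$element[is.na(a$radius)])
    stop("no radius for element(s): ", paste(bad, collapse = ", "))
  }
  bb <- unlist(table$backbone$charges)
  bbParents <- unlist(table$backbone$parents)
  offenders <- character(0)
  ## common PDB alias for the backbone amide proton
  a$name[a$name == "H"] <- "HN"
  reskey <- paste(a$chain, a$resno, sep = "|")
  for (k in unique(reskey)) {
    idx <- which(reskey == k)
    resname <- a$resname[idx[1]]
    isTitr <- resname %in% names(table$titratable)
    state <- NULL
    if (isTitr) {
      protOnly <- setdiff(names(unlist(table$titratable[[resname]]$protonated)),
                          names(unlist(table$titratable[[resname]]$deprotonated)))
      state <- if (length(protOnly) && any(protOnly %in% a$name[idx]))
        "protonated" else .defaultState(table, resname)
    }
    vc <- .variantCharges(table, resname,
                          if (is.null(state)) "charges" else state)
    if (is.null(vc)) {
      offenders <- c(offenders, paste0("residue ", resname, " ", k))
      next
    }
    side <- vc$charges
    parents <- c(bbParents, vc$parents)
    ## side-chain map overrides backbone for overlapping names (termini)
    full <- c(bb[setdiff(names(bb), names(side))], side)
    if (resname == "PRO")  # no amide proton; CD carries its charge
      full <- full[setdiff(names(full), "HN")]
    present <- a$name[idx]
    unknown <- setdiff(present, names(full))
    if (length(unknown))
      offenders <- c(offenders,
                     paste0("atom ", unknown, " in ", resname, " ", k))
    hit <- match(present, names(full))
    a$charge[idx][!is.na(hit)] <- unname(full[hit[!is.na(hit)]])
    ## collapse charges of absent hydrogens onto their parents
    ## collapse charges of absent hydrogens onto their parents; absent heavy
    ## atoms are left out (the formal-charge audit below catches any net
    ## inconsistency)
    missing <- setdiff(names(full), present)
    for (m in missing) {
      if (abs(full[[m]]) < 1e-12 || !m %in% names(parents)) next
      par <- parents[[m]]
      if (par %in% present) {
        j <- idx[match(par, present)]
        a$charge[j] <- a$charge[j] + full[[m]]
      }
    }
  }
  if (length(offenders))
    stop("unparameterized entries (no silent zero-charge): ",
         paste(offenders, collapse = "; "))
  out <- structure
  out@atoms <- a
  ## per-residue formal-charge audit
  chk <- residueChargeAudit(out, table)
  bad <- chk[abs(chk$net - chk$formal) > 1e-6, , drop = FALSE]
  if (nrow(bad))
    stop("residue net charge differs from formal charge: ",
         paste(sprintf("%s %s:%d (net %.4f, formal %d)", bad$resname,
                       bad$chain, bad$resno, bad$net, bad$formal),
               collapse = "; "))
  out
}

#' Per-residue net versus formal charges
#'
#' @param structure parameterized structure
#' @param table parameter table
#' @return data.frame with chain, resno, resname, net, formal
#' @export
residueChargeAudit <- function(structure, table = loadParameterTable()) {
  a <- atoms(structure)
  key <- paste(a$chain, a$resno, sep = "|")
  rows <- lapply(unique(key), function(k) {
    idx <- which(key == k)
    resname <- a$resname[idx[1]]
    formal <- if (resname %in% names(table$titratable)) {
      st <- .assignedState(a[idx, ], table, resname)
      cls <- table$titratable[[resname]]$class
      if (st == "deprotonated" && cls == "acid") -1L
      else if (st == "protonated" && cls == "base") 1L else 0L
    } else if (!is.null(table$residues[[resname]]$formal)) {
      as.integer(table$residues[[resname]]$formal)
    } else 0L
    data.frame(chain = a$chain[idx[1]], resno = a$resno[idx[1]],
               resname = resname, net = sum(a$charge[idx]), formal = formal)
  })
  do.call(rbind, rows)
}

.assignedState <- function(resAtoms, table, resname) {
  protOnly <- setdiff(names(unlist(table$titratable[[resname]]$protonated)),
                      names(unlist(table$titratable[[resname]]$deprotonated)))
  if (length(protOnly) && any(protOnly %in% resAtoms$name)) "protonated"
  else .defaultState(table, resname)
}

## ---------------------------------------------------------------------------
## Titratable sites
## ---------------------------------------------------------------------------

#' Site-selection policy
#'
#' @param include residue types recognized as titratable
#' @param tyrWhitelist residue numbers of tyrosines to titrate even when TYR
#'   is not in \code{include} (NULL = whitelist off; all TYR are included iff
#'   "TYR" is in \code{include})
#' @param termini include N-/C-termini (not implemented for termini lacking
#'   the terminal atoms)
#' @return a policy list
#' @export
sitePolicy <- function(include = c("ASP", "GLU", "LYS", "ARG", "TYR"),
                       tyrWhitelist = NULL, termini = FALSE) {
  list(include = include, tyrWhitelist = tyrWhitelist, termini = termini)
}

#' Identify titratable sites
#'
#' One site per residue whose type matches the policy, ordered by
#' (chain, residue number). Residues matching a titratable name but missing
#' required side-chain heavy atoms raise an error.
#'
#' @param structure parameterized structure
#' @param policy from \code{\link{sitePolicy}}
#' @param table parameter table
#' @return list of \linkS4class{TitratableSite}
#' @export
findTitratableSites <- function(structure, policy = sitePolicy(),
                                table = loadParameterTable()) {
  a <- atoms(structure)
  key <- paste(a$chain, a$resno, sep = "|")
  ord <- order(a$chain[!duplicated(key)], a$resno[!duplicated(key)])
  ukey <- unique(key)[ord]
  sites <- list()
  for (k in ukey) {
    idx <- which(key == k)
    resname <- a$resname[idx[1]]
    if (!resname %in% names(table$titratable)) next
    isTyr <- resname == "TYR"
    wanted <- resname %in% policy$include ||
      (isTyr && !is.null(policy$tyrWhitelist) &&
         a$resno[idx[1]] %in% policy$tyrWhitelist)
    if (isTyr && !is.null(policy$tyrWhitelist))
      wanted <- a$resno[idx[1]] %in% policy$tyrWhitelist
    if (!wanted) next
    t <- table$titratable[[resname]]
    dep <- unlist(t$deprotonated)
    heavy <- names(dep)[!grepl("^[0-9]*H", names(dep))]
    missing <- setdiff(heavy, a$name[idx])
    if (length(missing))
      stop("residue ", resname, " ", k, " is missing required side-chain ",
           "atoms: ", paste(missing, collapse = ", "))
    sites[[length(sites) + 1]] <- new(
      "TitratableSite",
      siteId = paste(a$chain[idx[1]], a$resno[idx[1]], resname, sep = ":"),
      residueType = resname, acidOrBase = t$class,
      modelPka = as.numeric(t$modelPka),
      protonatedCharges = unlist(t$protonated),
      deprotonatedCharges = dep,
      parents = unlist(t$parents),
      chain = a$chain[idx[1]], resno = as.integer(a$resno[idx[1]]))
  }
  sites
}

#' Atom indices of a site's variable-charge group
#'
#' @param structure parameterized structure
#' @param site a \linkS4class{TitratableSite}
#' @return integer row indices into \code{atoms(structure)}
#' @export
siteAtomIndices <- function(structure, site) {
  a <- atoms(structure)
  grp <- union(names(site@protonatedCharges),
               names(site@deprotonatedCharges))
  which(a$chain == site@chain & a$resno == site@resno & a$name %in% grp)
}

#' Charge distribution of a site in a given protonation state
#'
#' Returns the positions and charges of the site's variable group; charges of
#' hydrogens absent from the coordinates are collapsed onto their parent
#' heavy atoms so the net charge is exact.
#'
#' @param structure parameterized structure
#' @param site a \linkS4class{TitratableSite}
#' @param state "protonated", "deprotonated", or "difference"
#'   (protonated - deprotonated)
#' @return list(pos = m x 3 matrix, q = numeric)
#' @export
siteChargeSet <- function(structure, site,
                          state = c("protonated", "deprotonated",
                                    "difference")) {
  state <- match.arg(state)
  a <- atoms(structure)
  idx <- which(a$chain == site@chain & a$resno == site@resno)
  present <- a$name[idx]
  ch <- switch(state,
               protonated = site@protonatedCharges,
               deprotonated = site@deprotonatedCharges,
               difference = {
                 nm <- union(names(site@protonatedCharges),
                             names(site@deprotonatedCharges))
                 p <- site@protonatedCharges[nm]; p[is.na(p)] <- 0
                 d <- site@deprotonatedCharges[nm]; d[is.na(d)] <- 0
                 stats::setNames(p - d, nm)
               })
  q <- stats::setNames(numeric(length(present)), present)
  for (nm in names(ch)) {
    v <- ch[[nm]]
    if (nm %in% present) q[nm] <- q[nm] + v
    else if (abs(v) > 1e-12) {
      par <- site@parents[[nm]]
      if (is.null(par) || is.na(par) || !par %in% present)
        stop("site ", site@siteId, ": atom ", nm,
             " absent and no parent present to carry its charge")
      q[par] <- q[par] + v
    }
  }
  keep <- abs(q) > 1e-12 | names(q) %in% names(ch)
  sub <- idx[keep]
  list(pos = as.matrix(a[sub, c("x", "y", "z")]), q = unname(q[keep]))
}
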