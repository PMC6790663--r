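## File formats: extended XYZ for trajectories (comment line carries a cubic
## "Lattice=..." record), TSV for distribution functions (bin_lo, bin_hi,
## value, uncertainty plus a '#'-comment metadata block).

#' Write / read trajectories as extended XYZ
#'
#' Each frame is an atom count line, a comment line of the form
#' \code{Lattice="L 0 0 0 L 0 0 0 L" Properties=species:S:1:pos:R:3 Frame=k
#' Species=... N=... Temperature=...}, then one \code{element x y z} line per
#' site (nm). Reading requires the Lattice record and a cubic lattice;
#' coordinates round-trip to 1e-6 nm.
#'
#' @param trajectory A \linkS4class{Trajectory}.
#' @param path Output file.
#' @return \code{readXYZ}: a \linkS4class{Trajectory}.
#' @export
writeXYZ <- function(trajectory, path) {
  box <- trajectory@box
  m <- if (box@species == "water3") 3L else 1L
  natoms <- dim(trajectory@coords)[1]
  elems <- if (m == 3L) rep(c("O", "H", "H"), box@n) else rep("Ar", box@n)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(nFrames(trajectory))) {
    writeLines(as.character(natoms), con)
    writeLines(sprintf(
      paste0('Lattice="%.8f 0 0 0 %.8f 0 0 0 %.8f" ',
             "Properties=species:S:1:pos:R:3 Frame=%d Species=%s N=%d ",
             "Temperature=%.4f"),
      box@L, box@L, box@L, f, box@species, box@n, box@temperature), con)
    fr <- trajectory@coords[, , f]
    writeLines(sprintf("%s %.8f %.8f %.8f", elems, fr[, 1], fr[, 2], fr[, 3]),
               con)
  }
  invisible(path)
}

#' @rdname writeXYZ
#' @param temperature Box temperature to use if the file records none.
#' @export
readXYZ <- function(path, temperature = 298) {
  lines <- readLines(path)
  pos <- 1L
  frames <- list()
  L <- NA_real_; speciesName <- NULL; nmol <- NA_integer_; temp <- temperature
  frameNo <- 0L
  while (pos <= length(lines)) {
    if (!nzchar(trimws(lines[pos]))) { pos <- pos + 1L; next }
    natoms <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(natoms))
      stop("malformed XYZ: expected atom count at line ", pos)
    frameNo <- frameNo + 1L
    comment <- lines[pos + 1L]
    lat <- regmatches(comment,
                      regexpr('Lattice="[^"]*"', comment))
    if (!length(lat))
      stop("frame ", frameNo, ": missing Lattice record in comment line")
    nums <- as.numeric(strsplit(gsub('Lattice="|"', "", lat), "\\s+")[[1]])
    if (length(nums) != 9)
      stop("frame ", frameNo, ": Lattice must have 9 components")
    if (abs(nums[1] - nums[5]) > 1e-9 || abs(nums[5] - nums[9]) > 1e-9 ||
        any(abs(nums[-c(1, 5, 9)]) > 1e-12))
      stop("frame ", frameNo, ": only cubic lattices are supported")
    L <- nums[1]
    sp <- regmatches(comment, regexpr("Species=\\S+", comment))
    if (length(sp)) speciesName <- sub("Species=", "", sp)
    tp <- regmatches(comment, regexpr("Temperature=\\S+", comment))
    if (length(tp)) temp <- as.numeric(sub("Temperature=", "", tp))
    atomLines <- lines[(pos + 2L):(pos + 1L + natoms)]
    if (length(atomLines) != natoms || anyNA(atomLines))
      stop("frame ", frameNo, ": atom count mismatch")
    parts <- strsplit(trimws(atomLines), "\\s+")
    bad <- vapply(parts, length, 0L) < 4L
    if (any(bad))
      stop("frame ", frameNo, ": malformed atom line")
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (frameNo > 1L && nrow(xyz) != nrow(frames[[1]]))
      stop("frame ", frameNo, ": atom count differs from first frame")
    frames[[frameNo]] <- xyz
    firstElem <- vapply(parts, `[`, "", 1L)[1]
    if (is.null(speciesName))
      speciesName <- if (natoms %% 3L == 0L && firstElem == "O") "water3"
                     else "lj"
    pos <- pos + 2L + natoms
  }
  if (!frameNo) stop("no frames found in ", path)
  natoms <- nrow(frames[[1]])
  m <- if (speciesName == "water3") 3L else 1L
  if (is.na(nmol)) nmol <- natoms %/% m
  coords <- array(0, dim = c(natoms, 3, frameNo))
  for (f in seq_len(frameNo)) coords[, , f] <- frames[[f]]
  box <- new("SimulationBox", L = L, n = nmol, species = speciesName,
             temperature = temp)
  new("Trajectory", coords = coords, box = box,
      samplingSweeps = NA_real_, seed = NA_real_,
      meta = list(source = path))
}

#' Write / read distribution functions as TSV
#'
#' Four columns (\code{bin_lo}, \code{bin_hi}, \code{value},
#' \code{uncertainty}; 10 significant digits) preceded by a '#'-comment
#' block carrying the kind, units, scheme provenance (bin size or the
#' (i, j, k) triple with its definition ID), block count and the bulk
#' density. The round trip is lossless for fitness purposes.
#'
#' @param df A \linkS4class{DistributionFunction}.
#' @param path File path.
#' @return \code{readDF}: a \linkS4class{DistributionFunction}.
#' @export
writeDF <- function(df, path) {
  sc <- df@scheme
  hdr <- c(sprintf("# kind: %s", sc@kind),
           sprintf("# units: %s",
                   if (sc@kind == "radial") "nm, dimensionless"
                   else "kJ/mol, per kJ/mol per molecule"),
           sprintf("# n_blocks: %d", df@nBlocks))
  if (!is.null(sc@meta$bin_size))
    hdr <- c(hdr, sprintf("# bin_size: %.10g", sc@meta$bin_size))
  if (!is.null(sc@meta$id))
    hdr <- c(hdr, sprintf("# ijk: %d %d %d", sc@meta$i, sc@meta$j, sc@meta$k),
             sprintf("# id: %d", sc@meta$id))
  if (!is.null(df@meta$rho0))
    hdr <- c(hdr, sprintf("# rho0: %.10g", df@meta$rho0))
  if (!is.null(df@meta$nFrames))
    hdr <- c(hdr, sprintf("# n_frames: %d", df@meta$nFrames))
  if (!is.null(df@meta$nMolecules))
    hdr <- c(hdr, sprintf("# n_molecules: %d", df@meta$nMolecules))
  if (!is.null(df@meta$droppedFraction))
    hdr <- c(hdr, sprintf("# dropped_fraction: %.10g",
                          df@meta$droppedFraction))
  e <- sc@edges
  unc <- if (length(df@uncertainties)) df@uncertainties
         else rep(NA_real_, length(df@values))
  tab <- data.frame(bin_lo = sprintf("%.10g", e[-length(e)]),
                    bin_hi = sprintf("%.10g", e[-1]),
                    value = sprintf("%.10g", df@values),
                    uncertainty = ifelse(is.na(unc), "NA",
                                         sprintf("%.10g", unc)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(colnames(tab), collapse = "\t"), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeDF
#' @export
readDF <- function(path) {
  lines <- readLines(path)
  isMeta <- startsWith(lines, "#")
  meta <- list()
  for (l in lines[isMeta]) {
    kv <- strsplit(sub("^#\\s*", "", l), ":\\s*")[[1]]
    if (length(kv) == 2) meta[[kv[1]]] <- kv[2]
  }
  tab <- utils::read.table(text = lines[!isMeta], header = TRUE, sep = "\t")
  edges <- c(tab$bin_lo, tab$bin_hi[nrow(tab)])
  if (any(diff(edges) <= 0))
    stop("non-monotone bin edges in ", path)
  if (any(abs(tab$bin_hi[-nrow(tab)] - tab$bin_lo[-1]) > 1e-9))
    stop("bins are not contiguous in ", path)
  kind <- meta$kind
  if (is.null(kind) || !kind %in% c("radial", "energy"))
    stop("file must declare '# kind: radial|energy'")
  scMeta <- list()
  if (!is.null(meta$bin_size)) scMeta$bin_size <- as.numeric(meta$bin_size)
  if (!is.null(meta$ijk)) {
    ijk <- as.integer(strsplit(meta$ijk, "\\s+")[[1]])
    scMeta <- c(scMeta, list(i = ijk[1], j = ijk[2], k = ijk[3],
                             id = binDefinitionId(ijk[1], ijk[2], ijk[3])))
  }
  scheme <- new("BinScheme", kind = kind, edges = edges, meta = scMeta)
  unc <- suppressWarnings(as.numeric(tab$uncertainty))
  hasUnc <- !all(is.na(unc))
  dfMeta <- list()
  if (!is.null(meta$rho0)) dfMeta$rho0 <- as.numeric(meta$rho0)
  if (!is.null(meta$n_frames)) dfMeta$nFrames <- as.integer(meta$n_frames)
  if (!is.null(meta$n_molecules))
    dfMeta$nMolecules <- as.integer(meta$n_molecules)
  if (!is.null(meta$dropped_fraction))
    dfMeta$droppedFraction <- as.numeric(meta$dropped_fraction)
  new("DistributionFunction", scheme = scheme, values = tab$value,
      uncertainties = if (hasUnc) unc else numeric(0),
      nBlocks = if (!is.null(meta$n_blocks)) as.integer(meta$n_blocks) else 0L,
      meta = dfMeta)
}
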