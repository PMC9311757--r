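## Plain-text interchange formats.
##
## Conformers: multi-frame XYZ plus a sidecar whitespace table
## "index element charge vdw_radius mass"; PDB is accepted read-only
## (multi-model, via bio3d).
##
## FES grids: '#'-prefixed header lines, then rows "cv1 z F" with cv1
## varying fastest; blank lines between z blocks are tolerated.  Values are
## written with 17 significant digits so round trips are exact.

.fmtNum <- function(x) sprintf("%.17g", x)

#' Write / read a conformer ensemble as multi-frame XYZ plus atom table
#'
#' `writeConformers()` writes every frame to a multi-frame XYZ file and a
#' sidecar whitespace table with per-atom element, charge (e), van der
#' Waals radius (Å) and mass (amu).  `readConformers()` reads the pair back
#' (round trips are exact to stored precision); with `format = "pdb"` a
#' (multi-model) PDB file is read instead, with charges/radii/masses taken
#' from the sidecar table if given, otherwise zero charge, 1.7 Å radius.
#'
#' @param x a [ConformerEnsemble-class].
#' @param xyzPath path of the coordinate file.
#' @param atomsPath path of the sidecar atom table.
#' @param format `"xyz"` (default) or `"pdb"` (read-only).
#' @return `readConformers()` returns a [ConformerEnsemble-class];
#'   `writeConformers()` returns the paths, invisibly.
#' @export
writeConformers <- function(x, xyzPath, atomsPath) {
  stopifnot(is(x, "ConformerEnsemble"))
  n <- nAtoms(x); nf <- nFrames(x)
  con <- file(xyzPath, "w"); on.exit(close(con))
  for (f in seq_len(nf)) {
    writeLines(as.character(n), con)
    writeLines(sprintf("frame %d", f), con)
    m <- frameCoords(x, f)
    writeLines(sprintf("%s %s %s %s", x@elements,
                       .fmtNum(m[, 1]), .fmtNum(m[, 2]), .fmtNum(m[, 3])),
               con)
  }
  at <- data.frame(index = seq_len(n), element = x@elements,
                   charge = .fmtNum(x@charges), vdw_radius = .fmtNum(x@radii),
                   mass = .fmtNum(x@masses))
  utils::write.table(at, atomsPath, quote = FALSE, row.names = FALSE)
  invisible(c(xyz = xyzPath, atoms = atomsPath))
}

#' @rdname writeConformers
#' @param path coordinate file to read (XYZ or PDB).
#' @export
readConformers <- function(path, atomsPath = NULL,
                           format = c("xyz", "pdb")) {
  format <- match.arg(format)
  at <- NULL
  if (!is.null(atomsPath)) {
    at <- utils::read.table(atomsPath, header = TRUE)
    need <- c("index", "element", "charge", "vdw_radius", "mass")
    if (!all(need %in% names(at)))
      stop("atom table must have columns: ", paste(need, collapse = " "))
    at <- at[order(at$index), ]
  }
  if (format == "pdb") {
    pdb <- bio3d::read.pdb(path, multi = TRUE)
    xyz <- pdb$xyz
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
    n <- ncol(xyz) / 3L
    nf <- nrow(xyz)
    coords <- array(0, c(n, 3L, nf))
    for (f in seq_len(nf))
      coords[, , f] <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE)
    el <- pdb$atom$elesy
    if (is.null(el) || all(is.na(el)) || all(el == ""))
      el <- substr(trimws(pdb$atom$elety), 1, 1)
  } else {
    parsed <- .readXYZ(path)
    coords <- parsed$coords
    el <- parsed$elements
    n <- dim(coords)[1]
  }
  n <- dim(coords)[1]
  if (!is.null(at) && nrow(at) != n)
    stop(sprintf("atom table has %d rows but coordinates have %d atoms",
                 nrow(at), n))
  new("ConformerEnsemble", coords = coords,
      charges = if (is.null(at)) rep(0, n) else as.numeric(at$charge),
      radii = if (is.null(at)) rep(1.7, n) else as.numeric(at$vdw_radius),
      masses = if (is.null(at)) rep(12.011, n) else as.numeric(at$mass),
      elements = if (is.null(at)) as.character(el) else
        as.character(at$element),
      metadata = list(source = path))
}

.readXYZ <- function(path) {
  lines <- readLines(path)
  i <- 1L; nline <- length(lines)
  frames <- list(); elements <- NULL
  while (i <= nline) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1L)
      stop(sprintf("%s: line %d: expected an atom count, got '%s'",
                   path, i, lines[i]))
    if (i + 1L + n > nline)
      stop(sprintf("%s: line %d: truncated frame (need %d atom lines)",
                   path, i, n))
    block <- lines[(i + 2L):(i + 1L + n)]
    toks <- strsplit(trimws(block), "[[:space:]]+")
    bad <- which(vapply(toks, length, 1L) < 4L)
    if (length(bad))
      stop(sprintf("%s: line %d: malformed atom line '%s'",
                   path, i + 1L + bad[1], block[bad[1]]))
    el <- vapply(toks, `[[`, "", 1L)
    xyz <- t(vapply(toks, function(t)
      suppressWarnings(as.numeric(t[2:4])), numeric(3)))
    if (any(is.na(xyz)))
      stop(sprintf("%s: line %d: non-numeric coordinate",
                   path, i + 1L + which(rowSums(is.na(xyz)) > 0)[1]))
    if (is.null(elements)) elements <- el
    else if (length(el) != length(elements))
      stop(sprintf("%s: line %d: frame atom count differs from first frame",
                   path, i))
    frames[[length(frames) + 1L]] <- xyz
    i <- i + 2L + n
  }
  if (!length(frames)) stop(path, ": no frames found")
  coords <- array(0, c(length(elements), 3L, length(frames)))
  for (f in seq_along(frames)) coords[, , f] <- frames[[f]]
  list(coords = coords, elements = elements)
}

#' Write / read a 2D free-energy surface as a plain-text grid
#'
#' The dialect: `#`-prefixed header lines (temperature is recorded there),
#' then whitespace rows `cv1 z F` with cv1 varying fastest and an optional
#' blank line between z blocks.  Masked cells are written as `inf`.
#' `readFES2D()` accepts arbitrary column order via `columns` and
#' normalizes row order; ragged grids raise an error naming the offending
#' block.
#'
#' @param x a [FES2D-class].
#' @param path file path.
#' @return `readFES2D()` returns a [FES2D-class]; `writeFES()` the path,
#'   invisibly.
#' @export
writeFES <- function(x, path) {
  stopifnot(is(x, "FES2D"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("# free-energy surface F(cv1, z), kcal/mol",
               sprintf("# temperature %.17g", x@temperature),
               sprintf("# grid %d %d", length(x@cv1), length(x@z)),
               "# columns cv1 z F"), con)
  vals <- x@values
  vals[x@mask] <- Inf
  for (j in seq_along(x@z)) {
    writeLines(sprintf("%s %s %s", .fmtNum(x@cv1), .fmtNum(x@z[j]),
                       .fmtNum(vals[, j])), con)
    writeLines("", con)
  }
  invisible(path)
}

#' @rdname writeFES
#' @param columns character, names and order of the data columns; any
#'   permutation of `c("cv1", "z", "F")`.
#' @param temperature K; overrides a `# temperature` header if given.
#' @export
readFES2D <- function(path, columns = c("cv1", "z", "F"),
                      temperature = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (!setequal(columns, c("cv1", "z", "F")))
    stop("columns must be a permutation of c('cv1', 'z', 'F')")
  lines <- readLines(path)
  hdr <- grep("^[[:space:]]*#", lines)
  if (is.null(temperature)) {
    tl <- grep("^#\\s*temperature\\b", lines[hdr], value = TRUE)
    temperature <- if (length(tl))
      as.numeric(sub("^#\\s*temperature\\s+", "", tl[1])) else 300
  }
  dat <- lines
  if (length(hdr)) dat[hdr] <- ""
  keep <- nzchar(trimws(dat))
  rows <- which(keep)
  toks <- strsplit(trimws(dat[keep]), "[[:space:]]+")
  nt <- vapply(toks, length, 1L)
  if (any(nt < 3L))
    stop(sprintf("%s: line %d: expected 3 columns, got %d",
                 path, rows[which(nt < 3L)[1]], nt[which(nt < 3L)[1]]))
  m <- matrix(NA_real_, length(toks), 3L)
  for (k in 1:3) {
    v <- vapply(toks, `[[`, "", k)
    v[v %in% c("inf", "Inf", "INF")] <- "Inf"
    v[v %in% c("-inf", "-Inf")] <- "-Inf"
    v[v %in% c("nan", "NaN", "NA")] <- "NaN"
    m[, k] <- suppressWarnings(as.numeric(v))
  }
  bad <- which(is.na(m[, match("cv1", columns)]) |
                 is.na(m[, match("z", columns)]))
  if (length(bad))
    stop(sprintf("%s: line %d: non-numeric grid coordinate",
                 path, rows[bad[1]]))
  cv1v <- m[, match("cv1", columns)]
  zv <- m[, match("z", columns)]
  fv <- m[, match("F", columns)]
  cv1 <- sort(unique(cv1v))
  z <- sort(unique(zv))
  if (length(cv1v) != length(cv1) * length(z)) {
    tab <- table(zv)
    off <- names(tab)[tab != length(cv1)][1]
    stop(sprintf(
      "%s: ragged grid: z block %s has %d cv1 rows, expected %d",
      path, off, tab[[off]], length(cv1)))
  }
  values <- matrix(NA_real_, length(cv1), length(z))
  ic <- match(cv1v, cv1); iz <- match(zv, z)
  if (anyDuplicated(cbind(ic, iz)))
    stop(path, ": duplicate grid rows")
  values[cbind(ic, iz)] <- fv
  mask <- !is.finite(values)
  values[mask] <- NA_real_
  new("FES2D", cv1 = cv1, z = z, values = values, mask = mask,
      temperature = temperature, metadata = list(source = path))
}

#' Write / read a 1D free-energy profile as two-column text
#'
#' `writeProfile()` writes `z F` rows (with headers recording temperature,
#' bulk windows and channel interval); `readProfile()` reads them back, or
#' any plain two-column `z F` file, re-referencing to the bulk if the
#' headers are absent.
#'
#' @param x a [FES1D-class].
#' @param path file path.
#' @return `readProfile()` returns a [FES1D-class].
#' @export
writeProfile <- function(x, path) {
  stopifnot(is(x, "FES1D"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("# one-dimensional free-energy profile F(z), kcal/mol",
               sprintf("# temperature %.17g", x@temperature),
               sprintf("# bulk_windows %s",
                       paste(.fmtNum(as.vector(t(x@bulkWindows))),
                             collapse = " ")),
               sprintf("# channel %s %s", .fmtNum(x@channel[1]),
                       .fmtNum(x@channel[2])),
               "# columns z F"), con)
  writeLines(sprintf("%s %s", .fmtNum(x@z), .fmtNum(x@values)), con)
  invisible(path)
}

#' @rdname writeProfile
#' @param temperature K, used when the file has no temperature header.
#' @param bulkFraction fraction of the z range treated as bulk at each end
#'   when the file has no bulk-window header.
#' @export
readProfile <- function(path, temperature = 300, bulkFraction = 0.2) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  hdr <- lines[grepl("^\\s*#", lines)]
  getHdr <- function(key) {
    h <- grep(paste0("^#\\s*", key, "\\b"), hdr, value = TRUE)
    if (length(h)) as.numeric(strsplit(
      trimws(sub(paste0("^#\\s*", key), "", h[1])), "\\s+")[[1]])
    else NULL
  }
  tv <- getHdr("temperature"); if (!is.null(tv)) temperature <- tv[1]
  bw <- getHdr("bulk_windows")
  ch <- getHdr("channel")
  dat <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  m <- do.call(rbind, lapply(strsplit(trimws(dat), "\\s+"),
                             function(t) as.numeric(t[1:2])))
  if (any(is.na(m))) stop(path, ": non-numeric profile row")
  o <- order(m[, 1])
  z <- m[o, 1]; f <- m[o, 2]
  windows <- if (!is.null(bw)) matrix(bw, 2, 2, byrow = TRUE) else NULL
  .makeFES1D(z, f, temperature, bulkWindows = windows,
             bulkFraction = bulkFraction,
             channel = if (!is.null(ch)) ch else NULL,
             metadata = list(source = path))
}
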