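#' Read an extended XYZ file
#'
#' Parses the extended XYZ dialect: per-atom columns are declared in the
#' comment line as `Properties=species:S:1:pos:R:3[:name:R:k|:name:I:k]...`,
#' the cell as `Lattice="ax ay az bx by bz cx cy cz"` (row vectors), periodic
#' flags as `pbc="T T F"`, and scalars as `key=value` (notably `total_charge`
#' and `total_spin`). Declared per-atom arrays beyond species/pos (for example
#' `forces`, `charges`, `hirshfeld_ratios`) are attached to each system's
#' `info` list.
#'
#' @param path Path to the file.
#' @return A list of [atomic_system()] objects (possibly of length one).
#' @seealso [write_extxyz()]
#' @export
read_extxyz <- function(path) {
  lines <- readLines(path)
  out <- list()
  ln <- 1L
  while (ln <= length(lines)) {
    if (!nzchar(trimws(lines[ln]))) { ln <- ln + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[ln])))
    if (is.na(n) || n < 0L) {
      stop(sprintf("extxyz parse error at line %d: expected atom count, got '%s'",
                   ln, lines[ln]))
    }
    if (ln + 1L + n > length(lines) + 0L && n > 0L) {
      stop(sprintf("extxyz parse error at line %d: %d atom lines declared but file ends",
                   ln, n))
    }
    header <- if (ln + 1L <= length(lines)) lines[ln + 1L] else ""
    kv <- .parse_kv(header, ln + 1L)
    props <- .parse_properties(kv[["Properties"]], ln + 1L)
    atom_lines <- lines[(ln + 2L):(ln + 1L + n)]
    ncol_expected <- sum(vapply(props, function(p) p$width, integer(1)))
    toks <- strsplit(trimws(atom_lines), "\\s+")
    for (k in seq_along(toks)) {
      if (length(toks[[k]]) != ncol_expected) {
        stop(sprintf("extxyz parse error at line %d: expected %d columns, got %d",
                     ln + 1L + k, ncol_expected, length(toks[[k]])))
      }
    }
    tok <- do.call(rbind, toks)
    col <- 1L
    species <- NULL; pos <- NULL; extra <- list()
    for (p in props) {
      block <- tok[, col:(col + p$width - 1L), drop = FALSE]
      col <- col + p$width
      if (p$name == "species") {
        species <- block[, 1]
      } else if (p$name == "pos") {
        pos <- matrix(as.numeric(block), n, 3)
      } else {
        m <- if (p$type == "I") matrix(as.integer(block), n, p$width)
             else matrix(as.numeric(block), n, p$width)
        extra[[p$name]] <- if (p$width == 1L) m[, 1] else m
      }
    }
    cell <- NULL; pbc <- FALSE
    if (!is.null(kv[["Lattice"]])) {
      lat <- as.numeric(strsplit(trimws(kv[["Lattice"]]), "\\s+")[[1]])
      if (length(lat) != 9L) {
        stop(sprintf("extxyz parse error at line %d: Lattice needs 9 numbers", ln + 1L))
      }
      cell <- matrix(lat, 3, 3, byrow = TRUE)
      pbc <- TRUE
    }
    if (!is.null(kv[["pbc"]])) {
      pbc <- strsplit(trimws(kv[["pbc"]]), "\\s+")[[1]] %in% c("T", "TRUE", "true", "1")
    }
    q <- if (!is.null(kv[["total_charge"]])) as.numeric(kv[["total_charge"]]) else 0
    s <- if (!is.null(kv[["total_spin"]])) as.numeric(kv[["total_spin"]]) else 0
    sys <- atomic_system(pos, element_number(species), charge = q, spin = s,
                         cell = cell, pbc = pbc, info = extra)
    out[[length(out) + 1L]] <- sys
    ln <- ln + 2L + n
  }
  out
}

#' Write systems to an extended XYZ file
#'
#' @param systems A single [atomic_system()] or a list of them (frames).
#' @param path Output path.
#' @param arrays Optional character vector naming per-atom arrays from each
#'   system's `info` to write as extra columns (defaults to all numeric
#'   per-atom arrays present).
#' @param digits Number of significant digits (default 17: round-trip exact to
#'   double precision).
#' @return `path`, invisibly.
#' @export
write_extxyz <- function(systems, path, arrays = NULL, digits = 17) {
  if (inherits(systems, "atomic_system")) systems <- list(systems)
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- function(x) sprintf(paste0("%.", digits, "g"), x)
  for (sys in systems) {
    n <- n_atoms(sys)
    arr_names <- arrays
    if (is.null(arr_names)) {
      arr_names <- names(Filter(function(a) {
        (is.matrix(a) && nrow(a) == n) || (is.atomic(a) && length(a) == n)
      }, sys$info))
    }
    prop <- "species:S:1:pos:R:3"
    for (a in arr_names) {
      v <- sys$info[[a]]
      w <- if (is.matrix(v)) ncol(v) else 1L
      ty <- if (is.integer(v)) "I" else "R"
      prop <- paste0(prop, ":", a, ":", ty, ":", w)
    }
    header <- sprintf('Properties=%s total_charge=%s total_spin=%s', prop,
                      fmt(sys$charge), fmt(sys$spin))
    if (!is.null(sys$cell)) {
      header <- paste0(header, ' Lattice="',
                       paste(fmt(t(sys$cell)), collapse = " "), '"')
      header <- paste0(header, ' pbc="',
                       paste(ifelse(sys$pbc, "T", "F"), collapse = " "), '"')
    }
    writeLines(as.character(n), con)
    writeLines(header, con)
    cols <- cbind(element_symbol(sys$numbers),
                  matrix(fmt(sys$positions), n, 3))
    for (a in arr_names) {
      v <- sys$info[[a]]
      m <- if (is.matrix(v)) v else matrix(v, n, 1)
      cols <- cbind(cols, matrix(if (is.integer(v)) as.character(m) else fmt(m),
                                 n, ncol(m)))
    }
    writeLines(apply(cols, 1, paste, collapse = " "), con)
  }
  invisible(path)
}

# parse key=value tokens of an extxyz comment line (values may be quoted)
.parse_kv <- function(line, lineno) {
  kv <- list()
  pat <- '([A-Za-z_][A-Za-z0-9_]*)=("([^"]*)"|\\S+)'
  m <- gregexpr(pat, line, perl = TRUE)[[1]]
  if (m[1] == -1L) return(kv)
  starts <- as.integer(m); lens <- attr(m, "match.length")
  for (k in seq_along(starts)) {
    tokn <- substr(line, starts[k], starts[k] + lens[k] - 1L)
    eq <- regexpr("=", tokn, fixed = TRUE)
    key <- substr(tokn, 1L, eq - 1L)
    val <- substr(tokn, eq + 1L, nchar(tokn))
    val <- sub('^"', "", sub('"$', "", val))
    kv[[key]] <- val
  }
  kv
}

.parse_properties <- function(spec, lineno) {
  if (is.null(spec)) spec <- "species:S:1:pos:R:3"
  parts <- strsplit(spec, ":", fixed = TRUE)[[1]]
  if (length(parts) %% 3L != 0L) {
    stop(sprintf("extxyz parse error at line %d: malformed Properties '%s'",
                 lineno, spec))
  }
  props <- list()
  for (k in seq(1L, length(parts), by = 3L)) {
    w <- suppressWarnings(as.integer(parts[k + 2L]))
    if (is.na(w) || !parts[k + 1L] %in% c("S", "R", "I")) {
      stop(sprintf("extxyz parse error at line %d: malformed Properties '%s'",
                   lineno, spec))
    }
    props[[length(props) + 1L]] <- list(name = parts[k], type = parts[k + 1L],
                                        width = w)
  }
  props
}
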