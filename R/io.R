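#' Read outline coordinate files
#'
#' Reads a multi-specimen 2D outline file in either of two plain-text
#' dialects:
#'
#' * `"block-text"`: repeated blocks of one specimen-id line followed by one
#'   whitespace-delimited `x y` pair per line; blank lines between blocks are
#'   optional (a non-numeric line starts the next block).
#' * `"tps"`: standard TPS landmark format (`LM=n`, `n` coordinate lines,
#'   `ID=name`).
#'
#' Coordinates are Cartesian with y increasing upward; units are arbitrary
#' since Procrustes superimposition removes scale. Point order is preserved
#' exactly as read and no transformation is applied.
#'
#' @param path Path to the coordinate file.
#' @param dialect `"block-text"` (default) or `"tps"`.
#' @return A `coord_dataset`: a named list of p x 2 numeric matrices
#'   (columns `x`, `y`), one per specimen, names being the specimen ids.
#' @export
read_coordinates <- function(path, dialect = c("block-text", "tps")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("coordinate file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  specs <- if (dialect == "tps") parse_tps(lines) else parse_block_text(lines)
  if (length(specs) == 0L) stop("parse error: no specimen blocks found in ", path)
  validate_coord_dataset(specs)
}

# a line whose first token is numeric is a coordinate attempt; ids must
# not start with a number
is_coord_line <- function(x) {
  grepl("^\\s*[-+]?[0-9.]", x)
}

parse_block_text <- function(lines) {
  specs <- list()
  cur_id <- NULL
  cur_pts <- NULL
  cur_line0 <- NA_integer_
  flush <- function() {
    if (is.null(cur_id)) return(invisible())
    if (length(cur_pts) < 3L) {
      stop("parse error at line ", cur_line0, ": specimen '", cur_id,
           "' has fewer than 3 coordinate pairs")
    }
    if (!is.null(specs[[cur_id]])) stop("duplicate specimen id: ", cur_id)
    m <- do.call(rbind, cur_pts)
    colnames(m) <- c("x", "y")
    specs[[cur_id]] <<- m
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "") next
    if (is_coord_line(ln)) {
      if (is.null(cur_id)) stop("parse error at line ", i,
                                ": coordinate pair before any specimen id")
      vals <- suppressWarnings(as.numeric(strsplit(ln, "\\s+")[[1]]))
      if (length(vals) != 2L || anyNA(vals)) {
        stop("parse error at line ", i, ": non-numeric coordinate")
      }
      cur_pts[[length(cur_pts) + 1L]] <- vals
    } else {
      flush()
      cur_id <- ln
      cur_pts <- list()
      cur_line0 <- i
    }
  }
  flush()
  specs
}

parse_tps <- function(lines) {
  specs <- list()
  i <- 1L
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "") { i <- i + 1L; next }
    if (!grepl("^LM=", ln, ignore.case = TRUE)) {
      stop("parse error at line ", i, ": expected LM= record")
    }
    n <- suppressWarnings(as.integer(sub("^LM=", "", ln, ignore.case = TRUE)))
    if (is.na(n) || n < 3L) stop("parse error at line ", i, ": bad LM count")
    if (i + n > length(lines)) stop("parse error at line ", i, ": truncated block")
    pts <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("x", "y")))
    for (j in seq_len(n)) {
      vals <- suppressWarnings(as.numeric(strsplit(trimws(lines[i + j]), "\\s+")[[1]]))
      if (length(vals) != 2L || anyNA(vals)) {
        stop("parse error at line ", i + j, ": non-numeric coordinate")
      }
      pts[j, ] <- vals
    }
    i <- i + n + 1L
    id <- NULL
    while (i <= length(lines)) {
      ln <- trimws(lines[i])
      if (grepl("^ID=", ln, ignore.case = TRUE)) {
        id <- sub("^ID=", "", ln, ignore.case = TRUE)
        i <- i + 1L
        break
      }
      if (grepl("^LM=", ln, ignore.case = TRUE) || ln == "") break
      i <- i + 1L  # skip IMAGE=, SCALE=, ... records
    }
    if (is.null(id)) id <- paste0("specimen_", length(specs) + 1L)
    if (!is.null(specs[[id]])) stop("duplicate specimen id: ", id)
    specs[[id]] <- pts
  }
  specs
}

validate_coord_dataset <- function(specs) {
  stopifnot(is.list(specs), length(specs) > 0L)
  for (id in names(specs)) {
    m <- specs[[id]]
    if (!is.matrix(m) || ncol(m) != 2L || nrow(m) < 3L) {
      stop("specimen '", id, "' must be a matrix with >= 3 rows and 2 columns")
    }
    if (!all(is.finite(m))) stop("specimen '", id, "' has non-finite coordinates")
  }
  if (anyDuplicated(names(specs))) stop("duplicate specimen ids")
  structure(specs, class = "coord_dataset")
}

#' Write outline coordinates in block-text format
#'
#' Coordinates are written with 17 significant digits so that a write/read
#' round trip reproduces the doubles bit-exactly.
#'
#' @param dataset A `coord_dataset` (named list of p x 2 matrices).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coordinates <- function(dataset, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(dataset)) {
    writeLines(id, con)
    m <- dataset[[id]]
    writeLines(sprintf("%.17g %.17g", m[, 1], m[, 2]), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read a specimen trait table
#'
#' Expects delimited text with a header containing at least `species` and
#' `feeding_class` columns; `body_mass_g` is optional (mass-dependent
#' operations refuse to run without it). Feeding classes are folded to lower
#' case; any string other than `browser`/`grazer`/`unknown` is mapped to
#' `unknown` with a warning.
#'
#' @param path Path to a CSV/TSV file (separator sniffed from the header).
#' @return A data.frame with columns `species`, `feeding_class`, and
#'   `body_mass_g` if present.
#' @export
read_traits <- function(path) {
  if (!file.exists(path)) stop("trait table not found: ", path)
  hdr <- readLines(path, n = 1L)
  sep <- if (grepl("\t", hdr)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, strip.white = TRUE)
  names(df) <- tolower(names(df))
  if (!all(c("species", "feeding_class") %in% names(df))) {
    stop("trait table must have 'species' and 'feeding_class' columns")
  }
  if (anyDuplicated(df$species)) stop("duplicate species ids in trait table")
  cls <- tolower(trimws(df$feeding_class))
  bad <- !(cls %in% c("browser", "grazer", "unknown"))
  if (any(bad)) {
    warning("unrecognised feeding classes mapped to 'unknown': ",
            paste(unique(cls[bad]), collapse = ", "))
    cls[bad] <- "unknown"
  }
  df$feeding_class <- cls
  if ("body_mass_g" %in% names(df)) {
    m <- df$body_mass_g
    if (any(!is.na(m) & m <= 0)) stop("body_mass_g must be strictly positive")
  }
  df
}

#' Read a rooted phylogeny from a Newick file
#'
#' @param path Path to a Newick tree file.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) stop("tree file not found: ", path)
  tr <- tryCatch(suppressWarnings(ape::read.tree(path)), error = function(e) NULL)
  if (is.null(tr)) stop("unparsable Newick file: ", path)
  if (ape::Ntip(tr) < 2L) stop("tree must have >= 2 tips")
  if (anyDuplicated(tr$tip.label)) stop("duplicate tip labels")
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0)) {
    stop("negative branch lengths")
  }
  tr
}

# Canonical form for species-name matching: trim, underscores -> spaces,
# case-fold. Supertree tips conventionally use underscores.
normalise_species <- function(x) {
  tolower(gsub("_", " ", trimws(x)))
}

#' Reconcile coordinate data, trait table and tree to common species
#'
#' Restricts all inputs to the intersection of species ids (matched after
#' trimming, underscore/space unification and case-folding) and prunes the
#' tree to the matching tips, summing subtending branch lengths. A report of
#' dropped names is attached as the `"dropped"` attribute and emitted as a
#' message.
#'
#' @param dataset A `coord_dataset`.
#' @param traits A trait table from [read_traits()].
#' @param tree Optional `phylo` tree (or `NULL`).
#' @return A list with elements `dataset`, `traits`, `tree` (NULL if absent).
#' @export
reconcile <- function(dataset, traits, tree = NULL) {
  key_d <- normalise_species(names(dataset))
  key_t <- normalise_species(traits$species)
  keep <- intersect(key_d, key_t)
  if (!is.null(tree)) keep <- intersect(keep, normalise_species(tree$tip.label))
  if (length(keep) == 0L) stop("no species shared by all inputs")
  dropped <- unique(c(
    names(dataset)[!(key_d %in% keep)],
    traits$species[!(key_t %in% keep)],
    if (!is.null(tree)) tree$tip.label[!(normalise_species(tree$tip.label) %in% keep)]
  ))
  ord_d <- match(keep, key_d)
  out_d <- validate_coord_dataset(unclass(dataset)[ord_d])
  out_t <- traits[match(keep, key_t), , drop = FALSE]
  rownames(out_t) <- NULL
  out_tree <- NULL
  if (!is.null(tree)) {
    out_tree <- ape::keep.tip(tree, tree$tip.label[match(keep, normalise_species(tree$tip.label))])
  }
  if (length(dropped) > 0L) {
    message("reconcile: dropped ", length(dropped), " unmatched name(s): ",
            paste(utils::head(dropped, 10L), collapse = ", "),
            if (length(dropped) > 10L) ", ..." else "")
  }
  structure(list(dataset = out_d, traits = out_t, tree = out_tree),
            dropped = dropped)
}
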