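#' Read a taxon-by-character state matrix
#'
#' Characters are integer-coded. The habitat character uses 0 = pelagic,
#' 1 = benthic/demersal; a cornea character may use 0/1/2 (absent, one-part,
#' two-part); every other character is 0/1 (absent/present). Missing data
#' are written `?` or `ukn` and become `NA`. Any other token, and any code
#' outside a character's declared set, is rejected with row/column context.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"csv"`, `"tsv"` or `"nexus"`.
#'   NEXUS input is read with [ape::read.nexus.data()] (characters are then
#'   named `char1..charK` unless renamed).
#' @param codes Named list of allowed integer codes per character; entries
#'   default to `0:1`, except any character whose name contains "cornea"
#'   (case-insensitive), which defaults to `0:2`.
#' @return A `character_matrix`: integer matrix (taxa x characters, `NA` for
#'   missing) with attribute `codes`.
#' @export
read_character_matrix <- function(path, format = c("auto", "csv", "tsv",
                                                   "nexus"),
                                  codes = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", tsv = "tsv", txt = "tsv",
                     nex = "nexus", nexus = "nexus",
                     stop("cannot infer format from extension '", ext, "'",
                          call. = FALSE))
  }
  if (format == "nexus") {
    dat <- ape::read.nexus.data(path)
    taxa <- names(dat)
    k <- length(dat[[1L]])
    raw <- t(vapply(dat, function(v) as.character(v), character(k)))
    colnames(raw) <- paste0("char", seq_len(k))
  } else {
    df <- if (format == "csv") read.csv(path, check.names = FALSE,
                                        colClasses = "character")
          else read.delim(path, check.names = FALSE,
                          colClasses = "character")
    if (ncol(df) < 2L)
      stop("matrix must have a taxon column and at least one character",
           call. = FALSE)
    taxa <- df[[1L]]
    raw <- as.matrix(df[, -1L, drop = FALSE])
  }
  dup <- unique(taxa[duplicated(taxa)])
  if (length(dup))
    stop("duplicate taxa: ", paste(dup, collapse = ", "), call. = FALSE)
  rownames(raw) <- taxa
  character_matrix(raw, codes = codes)
}

#' Construct and validate a character matrix from raw string codes
#'
#' @param raw Character or integer matrix with taxa as row names.
#' @inheritParams read_character_matrix
#' @return A validated `character_matrix`.
#' @export
character_matrix <- function(raw, codes = NULL) {
  raw <- as.matrix(raw)
  if (is.null(rownames(raw)) || is.null(colnames(raw)))
    stop("matrix needs taxon row names and character column names",
         call. = FALSE)
  chars <- colnames(raw)
  full_codes <- lapply(chars, function(ch) {
    if (!is.null(codes) && ch %in% names(codes)) as.integer(codes[[ch]])
    else if (grepl("cornea", ch, ignore.case = TRUE)) 0:2
    else 0:1
  })
  names(full_codes) <- chars
  out <- matrix(NA_integer_, nrow(raw), ncol(raw),
                dimnames = dimnames(raw))
  for (j in seq_along(chars)) {
    v <- trimws(as.character(raw[, j]))
    miss <- v %in% c("?", "ukn", "NA", "") | is.na(v)
    num <- suppressWarnings(as.integer(v))
    bad <- !miss & (is.na(num) | !(num %in% full_codes[[j]]))
    if (any(bad)) {
      i <- which(bad)[1L]
      stop("invalid state '", v[i], "' for character '", chars[j],
           "', taxon '", rownames(raw)[i], "'", call. = FALSE)
    }
    out[, j] <- ifelse(miss, NA_integer_, num)
  }
  structure(out, codes = full_codes, class = c("character_matrix",
                                               class(out)))
}

#' @export
print.character_matrix <- function(x, ...) {
  cat("Character matrix: ", nrow(x), " taxa x ", ncol(x),
      " characters (", sum(is.na(x)), " missing cells)\n", sep = "")
  print(utils::head(unclass(x)))
  invisible(x)
}

#' Write a character matrix back to CSV/TSV
#'
#' Missing cells are written as `?`; round-trips with
#' [read_character_matrix()].
#'
#' @param x A `character_matrix`.
#' @param path Output path.
#' @param sep Field separator (`","` or `"\t"`).
#' @export
write_character_matrix <- function(x, path, sep = ",") {
  m <- unclass(x)
  out <- cbind(taxon = rownames(m),
               apply(m, 2, function(v) ifelse(is.na(v), "?",
                                              as.character(v))))
  write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract a character as a binary trait
#'
#' Multi-state presence characters are collapsed to presence/absence: a
#' cornea coded 0/1/2 maps `{0 -> 0, 1 -> 1, 2 -> 1}` (any cornea counts as
#' present); characters that are already binary are identity-mapped.
#' Missing values are preserved.
#'
#' @param matrix A `character_matrix`.
#' @param character Character (column) name.
#' @return A `binary_trait`: list with `name`, `tip_states` (named integer
#'   vector of 0/1/`NA` over the taxa) and `binarization_rule`.
#' @export
binarize <- function(matrix, character) {
  stopifnot(inherits(matrix, "character_matrix"))
  if (!character %in% colnames(matrix))
    stop("unknown character '", character, "'", call. = FALSE)
  v <- unclass(matrix)[, character]
  codes <- attr(matrix, "codes")[[character]]
  if (max(codes) > 1L) {
    states <- ifelse(is.na(v), NA_integer_, as.integer(v >= 1L))
    rule <- "presence: {0 -> 0, >=1 -> 1}"
  } else {
    states <- v
    rule <- "identity"
  }
  binary_trait(character, states, rule)
}

#' Construct a binary trait from named tip states
#'
#' @param name Trait name.
#' @param tip_states Named vector of 0/1/`NA` over taxa.
#' @param binarization_rule Provenance string for the mapping applied.
#' @return A `binary_trait`.
#' @export
binary_trait <- function(name, tip_states, binarization_rule = "identity") {
  taxa <- names(tip_states)
  if (is.null(taxa)) stop("tip states must be named by taxon", call. = FALSE)
  tip_states <- as.integer(tip_states)
  names(tip_states) <- taxa
  ok <- is.na(tip_states) | tip_states %in% c(0L, 1L)
  if (!all(ok))
    stop("binary trait '", name, "' has non-binary states", call. = FALSE)
  structure(list(name = name, tip_states = tip_states,
                 binarization_rule = binarization_rule),
            class = "binary_trait")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.binary_trait <- function(x, ...) {
  tab <- table(factor(x$tip_states, levels = 0:1), useNA = "ifany")
  cat("Binary trait '", x$name, "' (", x$binarization_rule, "): ",
      tab[1L], " x 0, ", tab[2L], " x 1, ",
      sum(is.na(x$tip_states)), " missing\n", sep = "")
  invisible(x)
}

#' Align a trait to a tree's tip set
#'
#' Tips present in the tree but absent from the trait become missing (with
#' a warning); taxa absent from the tree are dropped.
#'
#' @param trait A `binary_trait`.
#' @param tree A `phylo`.
#' @return Integer vector of 0/1/`NA` ordered as `tree$tip.label`.
#' @export
align_trait_to_tree <- function(trait, tree) {
  stopifnot(inherits(trait, "binary_trait"))
  out <- trait$tip_states[tree$tip.label]
  names(out) <- tree$tip.label
  absent <- setdiff(tree$tip.label, names(trait$tip_states))
  if (length(absent))
    warning("tip(s) without trait data treated as missing: ",
            paste(absent, collapse = ", "), call. = FALSE)
  out
}
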