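#' Load a Gaussian basis set
#'
#' Reads a basis-set definition from the plain-text library bundled with the
#' package (or from a user file of the same format). Shells are spherical
#' (pure) up to f. `SP` blocks are split into an S and a P shell sharing
#' exponents.
#'
#' @param name basis name (file `<name>.txt` under `inst/extdata/basis`) or a
#'   path to a basis file
#' @return a `qc_basis` object: list of per-element shell lists
#' @export
load_basis <- function(name) {
  path <- if (file.exists(name)) name else
    system.file("extdata", "basis", paste0(tolower(name), ".txt"), package = "vpdft")
  if (!nzchar(path) || !file.exists(path))
    stop("basis set not found: ", name)
  ln <- readLines(path)
  ln <- trimws(ln)
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  lmap <- c(S = 0L, P = 1L, D = 2L, F = 3L)
  elements <- list()
  i <- 1
  while (i <= length(ln)) {
    el <- ln[i]; i <- i + 1
    shells <- list()
    while (i <= length(ln) && ln[i] != "*") {
      typ <- toupper(ln[i]); i <- i + 1
      rows <- list()
      while (i <= length(ln) && grepl("^[-0-9]", ln[i])) {
        rows[[length(rows) + 1L]] <- as.numeric(strsplit(ln[i], "\\s+")[[1]])
        i <- i + 1
      }
      m <- do.call(rbind, rows)
      if (typ == "SP") {
        shells[[length(shells) + 1L]] <- list(l = 0L, exp = m[, 1], coef = m[, 2])
        shells[[length(shells) + 1L]] <- list(l = 1L, exp = m[, 1], coef = m[, 3])
      } else {
        if (!typ %in% names(lmap)) stop("unknown shell type ", typ)
        shells[[length(shells) + 1L]] <- list(l = lmap[[typ]], exp = m[, 1], coef = m[, 2])
      }
    }
    i <- i + 1 # skip "*"
    elements[[el]] <- shells
  }
  structure(list(name = tolower(basename(sub("\\.txt$", "", path))), elements = elements),
            class = "qc_basis")
}

#' @export
print.qc_basis <- function(x, ...) {
  cat("Basis set", x$name, "with elements:", paste(names(x$elements), collapse = " "), "\n")
  invisible(x)
}
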