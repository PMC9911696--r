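#' Parse a dot-bracket secondary structure
#'
#' Matches round brackets into base pairs and groups consecutive pairs into
#' helices (maximal stacks).  Only nested structures are supported: any
#' additional bracket layer (`[]`, `{}`, `<>`) denotes a pseudoknot and is
#' rejected.
#'
#' @param db Dot-bracket string using `.`, `(` and `)`.
#' @param seq RNA sequence (characters AUGC), same length as `db`.
#'
#' @return An object of class `secondary_structure`: a list with `seq`, `n`,
#'   `pairs` (two-column integer matrix, 1-based, i < j, ordered by i),
#'   `paired` (partner index per nucleotide, `NA` if unpaired) and `helices`
#'   (data frame with columns `helix`, `i`, `j`, one row per pair).
#' @examples
#' ss <- parse_dotbracket("((..))", "GGAACC")
#' ss$pairs
#' @export
parse_dotbracket <- function(db, seq) {
  stopifnot(is.character(db), length(db) == 1L,
            is.character(seq), length(seq) == 1L)
  if (nchar(db) != nchar(seq)) {
    stop("dot-bracket string and sequence must have equal length")
  }
  ch <- strsplit(db, "")[[1]]
  if (any(ch %in% c("[", "]", "{", "}", "<", ">"))) {
    stop("pseudoknot bracket layers are not supported")
  }
  if (!all(ch %in% c(".", "(", ")"))) {
    stop("parse error: dot-bracket may contain only '.', '(' and ')'")
  }
  sq <- toupper(seq)
  if (!all(strsplit(sq, "")[[1]] %in% c("A", "U", "G", "C", "N"))) {
    stop("sequence may contain only A, U, G, C (or N)")
  }
  n <- length(ch)
  stack <- integer(0)
  pairs <- matrix(integer(0), ncol = 2)
  po <- vector("list", n)
  k <- 0L
  op <- integer(n)
  for (i in seq_len(n)) {
    if (ch[i] == "(") {
      k <- k + 1L
      op[k] <- i
    } else if (ch[i] == ")") {
      if (k == 0L) stop("parse error: unbalanced brackets")
      pairs <- rbind(pairs, c(op[k], i))
      k <- k - 1L
    }
  }
  if (k != 0L) stop("parse error: unbalanced brackets")
  if (nrow(pairs) > 0) {
    pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  }
  paired <- rep(NA_integer_, n)
  if (nrow(pairs) > 0) {
    paired[pairs[, 1]] <- pairs[, 2]
    paired[pairs[, 2]] <- pairs[, 1]
  }
  # helices: maximal runs of consecutive stacked pairs
  helix <- integer(nrow(pairs))
  h <- 0L
  for (t in seq_len(nrow(pairs))) {
    if (t > 1 && pairs[t, 1] == pairs[t - 1, 1] + 1L &&
        pairs[t, 2] == pairs[t - 1, 2] - 1L) {
      helix[t] <- h
    } else {
      h <- h + 1L
      helix[t] <- h
    }
  }
  helices <- data.frame(helix = helix,
                        i = pairs[, 1], j = pairs[, 2])
  ss <- list(seq = sq, n = n, pairs = pairs, paired = paired,
             helices = helices, n_helices = h)
  class(ss) <- "secondary_structure"
  ss
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat("Secondary structure:", x$n, "nt,", nrow(x$pairs), "pairs,",
      x$n_helices, "helices\n")
  invisible(x)
}

# Summary table of helices: one row per helix with outer/inner pair indices.
helix_table <- function(ss) {
  if (ss$n_helices == 0) {
    return(data.frame(helix = integer(0), oi = integer(0), oj = integer(0),
                      ii = integer(0), ij = integer(0), len = integer(0)))
  }
  do.call(rbind, lapply(split(ss$helices, ss$helices$helix), function(d) {
    data.frame(helix = d$helix[1], oi = min(d$i), oj = max(d$j),
               ii = max(d$i), ij = min(d$j), len = nrow(d))
  }))
}
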