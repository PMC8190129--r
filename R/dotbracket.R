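# Dot-bracket secondary structures.
#
# A secondary structure is a length plus a set of base pairs, each pair
# belonging to a bracket "layer": round brackets are layer 0 (the nested
# backbone structure), square/curly/angle brackets are layers 1-3 and house
# pseudoknot pairs that cross layer 0. Within a layer pairs must nest; a
# position may pair at most once across all layers (templates carry only
# canonical pairs, base triples are out of scope).

BRACKET_OPEN <- c("(", "[", "{", "<")
BRACKET_CLOSE <- c(")", "]", "}", ">")

#' Construct a secondary structure
#'
#' @param length number of nucleotides.
#' @param pairs data frame with integer columns `five`, `three`, `layer`
#'   (layer 0 = round brackets). May have zero rows.
#' @return object of class `rna_ss`.
#' @export
secondary_structure <- function(length, pairs = empty_pairs()) {
  length <- as.integer(length)
  if (is.matrix(pairs)) pairs <- as.data.frame(pairs)
  if (nrow(pairs) == 0) {
    pairs <- empty_pairs()
  } else {
    pairs <- data.frame(
      five = as.integer(pairs$five),
      three = as.integer(pairs$three),
      layer = as.integer(pairs$layer)
    )
    pairs <- pairs[order(pairs$five), , drop = FALSE]
    rownames(pairs) <- NULL
  }
  ss <- structure(list(length = length, pairs = pairs), class = "rna_ss")
  validate_ss(ss)
  ss
}

empty_pairs <- function() {
  data.frame(five = integer(0), three = integer(0), layer = integer(0))
}

validate_ss <- function(ss) {
  p <- ss$pairs
  if (ss$length < 0) stop("structure length must be >= 0")
  if (nrow(p) == 0) return(invisible(ss))
  if (any(p$five >= p$three)) stop("base pair must have five_prime < three_prime")
  if (any(p$five < 1L) || any(p$three > ss$length)) {
    stop("base pair positions outside [1, length]")
  }
  if (any(p$layer < 0L)) stop("bracket layer must be non-negative")
  pos <- c(p$five, p$three)
  if (anyDuplicated(pos)) {
    stop("position ", pos[duplicated(pos)][1L], " participates in more than one pair")
  }
  for (ly in unique(p$layer)) {
    q <- p[p$layer == ly, , drop = FALSE]
    if (nrow(q) < 2) next
    # crossing check: pairs (i,j), (k,l) with i < k < j < l
    for (a in seq_len(nrow(q) - 1L)) {
      k <- q$five[(a + 1L):nrow(q)]
      l <- q$three[(a + 1L):nrow(q)]
      if (any(k < q$three[a] & l > q$three[a])) {
        stop("crossing pairs within layer ", ly)
      }
    }
  }
  invisible(ss)
}

#' @export
print.rna_ss <- function(x, ...) {
  cat("RNA secondary structure: length", x$length, "with", nrow(x$pairs),
      "base pair(s)\n")
  if (x$length > 0 && x$length <= 200) cat(write_dotbracket(x), "\n")
  invisible(x)
}

#' @export
`==.rna_ss` <- function(e1, e2) {
  identical(e1$length, e2$length) &&
    nrow(e1$pairs) == nrow(e2$pairs) &&
    all(e1$pairs == e2$pairs)
}

#' Parse dot-bracket notation
#'
#' Parses a Vienna-style dot-bracket string into a secondary structure.
#' Four bracket families are recognised: `()` (layer 0), `[]` (layer 1),
#' `{}` (layer 2) and `<>` (layer 3); each family is matched with its own
#' stack, so within a family pairs always nest and distinct families can
#' carry pseudoknotted (crossing) pairs.
#'
#' @param text a dot-bracket string; whitespace is stripped.
#' @return an [secondary_structure()] object (`rna_ss`).
#' @export
#' @examples
#' parse_dotbracket("((..[[..))..]]")
parse_dotbracket <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- gsub("[[:space:]]", "", text)
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  bad <- which(!(chars %in% c(".", BRACKET_OPEN, BRACKET_CLOSE)))
  if (length(bad)) {
    stop("invalid character '", chars[bad[1]], "' at ", bad[1])
  }
  stacks <- rep(list(integer(0)), 4L)
  five <- integer(0); three <- integer(0); layer <- integer(0)
  for (i in seq_len(n)) {
    ch <- chars[i]
    if (ch == ".") next
    fam <- match(ch, BRACKET_OPEN)
    if (!is.na(fam)) {
      stacks[[fam]] <- c(stacks[[fam]], i)
    } else {
      fam <- match(ch, BRACKET_CLOSE)
      st <- stacks[[fam]]
      if (length(st) == 0L) {
        stop("unbalanced '", ch, "' at ", i)
      }
      five <- c(five, st[length(st)])
      three <- c(three, i)
      layer <- c(layer, fam - 1L)
      stacks[[fam]] <- st[-length(st)]
    }
  }
  for (fam in 1:4) {
    if (length(stacks[[fam]])) {
      stop("unbalanced '", BRACKET_OPEN[fam], "' opened at ", stacks[[fam]][1])
    }
  }
  secondary_structure(n, data.frame(five = five, three = three, layer = layer))
}

#' Write dot-bracket notation
#'
#' Inverse of [parse_dotbracket()]: serialises a secondary structure to a
#' dot-bracket string, one bracket family per layer.
#'
#' @param ss an `rna_ss` object.
#' @return single dot-bracket string.
#' @export
write_dotbracket <- function(ss) {
  stopifnot(inherits(ss, "rna_ss"))
  out <- rep(".", ss$length)
  p <- ss$pairs
  if (nrow(p)) {
    if (any(p$layer > 3L)) stop("cannot serialise layers beyond 3 (angle brackets)")
    out[p$five] <- BRACKET_OPEN[p$layer + 1L]
    out[p$three] <- BRACKET_CLOSE[p$layer + 1L]
  }
  paste(out, collapse = "")
}

# Pairing partner lookup: partner[i] = j if (i,j) paired in any layer, else NA.
pairing_vector <- function(ss, layer = NULL) {
  partner <- rep(NA_integer_, ss$length)
  p <- ss$pairs
  if (!is.null(layer)) p <- p[p$layer %in% layer, , drop = FALSE]
  partner[p$five] <- p$three
  partner[p$three] <- p$five
  partner
}
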