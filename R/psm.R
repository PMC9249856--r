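## PSM table parsing (Percolator-style tab-delimited search results).

#' Strip heavy-label modifications from an annotated peptide sequence
#'
#' Modification annotations follow the bracket dialect `X[+mass]` (an
#' optionally signed decimal after the modified residue, e.g.
#' `"PEPTIK[+6.0201]R"`). Heavy-lysine labels (+6.0201 on K) are counted and
#' removed; all other modifications (e.g. +15.9949 methionine oxidation) are
#' returned as retained mass shifts that do not alter the plain sequence.
#'
#' @param modifiedSequence Annotated sequence, optionally with Percolator
#'   flanking residues (`"K.PEPT[+79.97]IDEK.A"`).
#' @param labelShift Mass shift of the heavy label (Da); default +6.0201.
#' @param labelResidue Residue carrying the label; default `"K"`.
#' @param tol Matching tolerance for the label mass (Da).
#' @return List with `sequence` (plain residue letters), `heavyLysines`
#'   (count of label tokens removed) and `modifications` (data.frame of
#'   retained position/mass-shift pairs).
#' @export
#' @examples
#' stripHeavyLabel("AK[+6.0201]LK[+6.0201]R")  # AKLKR, 2 heavy lysines
#' stripHeavyLabel("ELVISM[+15.9949]K")        # oxidation retained, 0 labels
stripHeavyLabel <- function(modifiedSequence, labelShift = HEAVY_K_SHIFT,
                            labelResidue = "K", tol = 0.01) {
  s <- modifiedSequence
  ## drop Percolator flanking residues "X.SEQ.X" (X may be '-')
  if (grepl("^[A-Z-]\\.", s) && grepl("\\.[A-Z-]$", s))
    s <- substr(s, 3, nchar(s) - 2)
  plain <- character(0)
  pos <- integer(0); shift <- numeric(0)
  heavy <- 0L
  i <- 1; n <- nchar(s)
  while (i <= n) {
    ch <- substr(s, i, i)
    if (ch == "[") {
      close <- regexpr("\\]", substr(s, i, n))
      if (close < 0) stop("malformed modification annotation near: ",
                          substr(s, i, n))
      token <- substr(s, i + 1, i + close - 2)
      m <- suppressWarnings(as.numeric(token))
      if (is.na(m)) stop("malformed modification token: [", token, "]")
      if (length(plain) == 0)
        stop("modification annotation with no preceding residue: [", token, "]")
      if (abs(m - labelShift) <= tol &&
          plain[length(plain)] == labelResidue) {
        heavy <- heavy + 1L
      } else {
        pos <- c(pos, length(plain)); shift <- c(shift, m)
      }
      i <- i + close
    } else if (ch %in% LETTERS) {
      ## residue validity is enforced downstream at mass computation
      plain <- c(plain, ch)
      i <- i + 1
    } else {
      stop("unexpected character in sequence annotation: '", ch, "'")
    }
  }
  list(sequence = paste(plain, collapse = ""), heavyLysines = heavy,
       modifications = data.frame(position = pos, massShift = shift))
}

.findColumn <- function(nms, candidates) {
  hit <- which(tolower(nms) %in% candidates)
  if (length(hit)) hit[1] else NA_integer_
}

#' Parse a Percolator-style PSM table
#'
#' Reads a tab-delimited peptide-spectrum-match table, applies the q-value
#' threshold, removes decoy/contaminant accessions, strips heavy-label
#' annotations and counts heavy lysines. Column headers are matched
#' case-insensitively: sequence (`sequence`/`peptide`), `charge`, scan
#' (`scan`/`scannr`/`scan_num`/`scan_number`), q-value
#' (`q-value`/`q_value`/`qvalue`/`percolator q-value`), proteins
#' (`proteinids`/`protein`/`proteins`/`protein_id`), and optionally
#' retention time (`retention_time`/`rt`, minutes).
#'
#' @param path Path to the tab-delimited file.
#' @param qThreshold Retain rows with q-value <= this (default 0.01, the 1%
#'   FDR convention).
#' @param decoyPrefixes Accession prefixes marking decoy or contaminant
#'   entries to exclude.
#' @return data.frame with columns `sequence`, `modifiedSequence`, `charge`,
#'   `scan`, `rt` (NA if absent), `qValue`, `proteins`
#'   (semicolon-collapsed), `nProteins`, `heavyLysines`, `nLysine`,
#'   `modMassShift` (summed retained shifts). Unparsable rows are skipped
#'   with one warning giving the count.
#' @export
parsePsmTable <- function(path, qThreshold = 0.01,
                          decoyPrefixes = c("DECOY_", "CONTAM_")) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  nms <- names(tab)
  idx <- c(
    sequence = .findColumn(nms, c("sequence", "peptide")),
    charge   = .findColumn(nms, c("charge", "z")),
    scan     = .findColumn(nms, c("scan", "scannr", "scan_num", "scan_number")),
    q        = .findColumn(nms, c("q-value", "q_value", "qvalue",
                                  "percolator q-value")),
    proteins = .findColumn(nms, c("proteinids", "protein", "proteins",
                                  "protein_id"))
  )
  missing <- names(idx)[is.na(idx)]
  if (length(missing))
    stop("PSM table is missing required column(s): ",
         paste(missing, collapse = ", "))
  rtIdx <- .findColumn(nms, c("retention_time", "rt", "retentiontime"))

  n <- nrow(tab)
  if (n == 0)
    return(data.frame(sequence = character(0), modifiedSequence = character(0),
                      charge = integer(0), scan = integer(0), rt = numeric(0),
                      qValue = numeric(0), proteins = character(0),
                      nProteins = integer(0), heavyLysines = integer(0),
                      nLysine = integer(0), modMassShift = numeric(0)))

  rows <- vector("list", n)
  bad <- 0L
  for (r in seq_len(n)) {
    parsed <- tryCatch({
      modSeq <- as.character(tab[r, idx["sequence"]])
      z <- suppressWarnings(as.integer(tab[r, idx["charge"]]))
      scan <- suppressWarnings(as.integer(tab[r, idx["scan"]]))
      q <- suppressWarnings(as.numeric(tab[r, idx["q"]]))
      prot <- as.character(tab[r, idx["proteins"]])
      rt <- if (is.na(rtIdx)) NA_real_ else
        suppressWarnings(as.numeric(tab[r, rtIdx]))
      if (is.na(z) || z < 1 || is.na(q) || q < 0 || q > 1)
        stop("bad numeric field")
      stripped <- stripHeavyLabel(modSeq)
      accs <- strsplit(prot, "[;,[:space:]]+")[[1]]
      accs <- accs[nzchar(accs)]
      keepAcc <- accs[!Reduce(`|`, lapply(decoyPrefixes, startsWith,
                                          x = accs), accumulate = FALSE)]
      data.frame(
        sequence = stripped$sequence, modifiedSequence = modSeq,
        charge = z, scan = scan, rt = rt, qValue = q,
        proteins = paste(keepAcc, collapse = ";"),
        nProteins = length(keepAcc),
        heavyLysines = stripped$heavyLysines,
        nLysine = sum(strsplit(stripped$sequence, "")[[1]] == "K"),
        modMassShift = sum(stripped$modifications$massShift),
        allDecoy = length(keepAcc) == 0,
        stringsAsFactors = FALSE)
    }, error = function(e) NULL)
    if (is.null(parsed)) bad <- bad + 1L else rows[[r]] <- parsed
  }
  if (bad > 0)
    warning(bad, " unparsable PSM row(s) skipped")
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) return(parsePsmTable0())
  out <- out[out$qValue <= qThreshold & !out$allDecoy, , drop = FALSE]
  out$allDecoy <- NULL
  rownames(out) <- NULL
  stopifnot(all(out$heavyLysines <= out$nLysine))
  out
}

parsePsmTable0 <- function() {
  data.frame(sequence = character(0), modifiedSequence = character(0),
             charge = integer(0), scan = integer(0), rt = numeric(0),
             qValue = numeric(0), proteins = character(0),
             nProteins = integer(0), heavyLysines = integer(0),
             nLysine = integer(0), modMassShift = numeric(0))
}
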