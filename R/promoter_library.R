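#' Canonical E. coli sigma70 hexamer consensus sequences
#'
#' `CONSENSUS_MINUS35` (TTGACA) and `CONSENSUS_MINUS10` (TATAAT) are the
#' consensus sequences against which library parts are annotated.
#'
#' @format Length-1 character vectors.
#' @export
CONSENSUS_MINUS35 <- "TTGACA"

#' @rdname CONSENSUS_MINUS35
#' @export
CONSENSUS_MINUS10 <- "TATAAT"

#' Create a promoter part (-35 or -10 hexamer)
#'
#' A promoter part is one of the two hexameric elements recognized by
#' sigma70-bound RNA polymerase. By convention -35 sites carry lowercase
#' single-letter labels and -10 sites uppercase ones, so that a variant such
#' as `dE` names its -35 ("d") and -10 ("E") sites.
#'
#' @param label Short identifier, unique within its kind.
#' @param kind `"minus35"` or `"minus10"`.
#' @param sequence 6-base DNA string over A, C, G, T.
#' @return An object of class `promoter_part`.
#' @examples
#' promoter_part("d", "minus35", "TTTACA")
#' @export
promoter_part <- function(label, kind = c("minus35", "minus10"), sequence) {
  kind <- match.arg(kind)
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  sequence <- toupper(sequence)
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) != 6L)
    stop("'sequence' must be a single 6-base string, got: ", sequence)
  if (grepl("[^ACGT]", sequence))
    stop("'sequence' may only contain A, C, G, T: ", sequence)
  structure(list(label = label, kind = kind, sequence = sequence),
            class = "promoter_part")
}

#' @export
print.promoter_part <- function(x, ...) {
  cat(sprintf("<promoter_part> %s [%s] %s\n", x$label, x$kind, x$sequence))
  invisible(x)
}

#' Create an operator site
#'
#' An operator is a transcription-factor binding site within the promoter:
#' activator operators sit immediately upstream of the -35 site, repressor
#' operators in the spacer between the hexamers, at the +1 position, or far
#' upstream (~ -400).
#'
#' @param name Identifier, e.g. `"AraO"`, `"LacO1"`, `"LacOsym"`, `"TetO2"`.
#' @param role `"activator"` or `"repressor"`.
#' @param position Signed 0-based offset in bases relative to the +1
#'   transcription start; negative is upstream.
#' @param sequence DNA string or `NA` placeholder (the occupancy model reads
#'   operator identity and role only, never base content).
#' @return An object of class `operator_site`.
#' @export
operator_site <- function(name, role = c("activator", "repressor"),
                          position, sequence = NA_character_) {
  role <- match.arg(role)
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(position), length(position) == 1L)
  structure(list(name = name, role = role, position = as.integer(position),
                 sequence = sequence),
            class = "operator_site")
}

#' Define a promoter architecture
#'
#' The scaffold shared by all members of a combinatorial library: exactly one
#' activator operator immediately upstream of the -35 site, optional repressor
#' operators in the spacer, optional auxiliary operators (downstream of +1 or
#' far upstream), and a fixed downstream reporter context.
#'
#' @param activator_operator An [operator_site()] with role `"activator"`.
#' @param spacer_operators List of repressor [operator_site()]s in the spacer.
#' @param auxiliary_operators List of extra [operator_site()]s.
#' @param reporter Identifier of the fixed downstream reporter context.
#' @return An object of class `promoter_architecture`.
#' @export
promoter_architecture <- function(activator_operator,
                                  spacer_operators = list(),
                                  auxiliary_operators = list(),
                                  reporter = "yfp") {
  if (!inherits(activator_operator, "operator_site") ||
      activator_operator$role != "activator")
    stop("'activator_operator' must be an operator_site with role 'activator'")
  for (op in c(spacer_operators, auxiliary_operators))
    if (!inherits(op, "operator_site"))
      stop("spacer/auxiliary operators must be operator_site objects")
  for (op in spacer_operators)
    if (op$role != "repressor")
      stop("spacer operators must have role 'repressor': ", op$name)
  structure(list(activator_operator = activator_operator,
                 spacer_operators = spacer_operators,
                 auxiliary_operators = auxiliary_operators,
                 reporter = reporter),
            class = "promoter_architecture")
}

# "AraO" / "AraC" -> "ara"; "LasO" -> "las"; prefix used in variant ids
activator_prefix <- function(architecture) {
  nm <- architecture$activator_operator$name
  tolower(gsub("(O|R|C)[0-9]*$", "", nm))
}

#' Assemble a combinatorial -35 x -10 promoter library
#'
#' Forms the full Cartesian product of the supplied -35 and -10 parts on a
#' common architecture, in deterministic order: -35 labels outer, -10 labels
#' inner, each alphabetical.
#'
#' @param minus35_list,minus10_list Lists of [promoter_part()]s of the
#'   matching kind, labels unique within each list.
#' @param architecture A [promoter_architecture()].
#' @return A data frame of class `promoter_library` with one row per variant:
#'   columns `id`, `minus35`, `minus10`, `minus35_seq`, `minus10_seq`. The
#'   architecture is attached as attribute `"architecture"`.
#' @examples
#' arch <- promoter_architecture(operator_site("AraO", "activator", -60))
#' lib <- assemble_library(default_minus35_parts(), default_minus10_parts(), arch)
#' nrow(lib)  # 48
#' @export
assemble_library <- function(minus35_list, minus10_list, architecture) {
  check_parts <- function(parts, kind) {
    for (p in parts) {
      if (!inherits(p, "promoter_part") || p$kind != kind)
        stop("all parts must be promoter_part objects of kind '", kind, "'")
    }
    labs <- vapply(parts, `[[`, "", "label")
    dup <- labs[duplicated(labs)]
    if (length(dup))
      stop("duplicate ", kind, " label(s): ", paste(unique(dup), collapse = ", "))
    labs
  }
  labs35 <- check_parts(minus35_list, "minus35")
  labs10 <- check_parts(minus10_list, "minus10")
  if (!inherits(architecture, "promoter_architecture"))
    stop("'architecture' must be a promoter_architecture")

  o35 <- order(labs35)
  o10 <- order(labs10)
  minus35_list <- minus35_list[o35]
  minus10_list <- minus10_list[o10]
  labs35 <- labs35[o35]
  labs10 <- labs10[o10]

  n35 <- length(labs35); n10 <- length(labs10)
  if (n35 == 0L || n10 == 0L) {
    lib <- data.frame(id = character(), minus35 = character(),
                      minus10 = character(), minus35_seq = character(),
                      minus10_seq = character(), stringsAsFactors = FALSE)
  } else {
    i35 <- rep(seq_len(n35), each = n10)
    i10 <- rep(seq_len(n10), times = n35)
    prefix <- activator_prefix(architecture)
    lib <- data.frame(
      id = paste0(prefix, "-", labs35[i35], labs10[i10]),
      minus35 = labs35[i35],
      minus10 = labs10[i10],
      minus35_seq = vapply(minus35_list[i35], `[[`, "", "sequence"),
      minus10_seq = vapply(minus10_list[i10], `[[`, "", "sequence"),
      stringsAsFactors = FALSE
    )
  }
  attr(lib, "architecture") <- architecture
  class(lib) <- c("promoter_library", "data.frame")
  lib
}

#' Count mismatches to a consensus sequence
#'
#' Hamming distance between a promoter part (or plain sequence) and a
#' consensus of equal length; the number of bases that would be underlined in
#' a consensus-annotated library listing.
#'
#' @param site A [promoter_part()] or a DNA string.
#' @param consensus Consensus DNA string of equal length; defaults to the
#'   canonical sigma70 consensus of the part's kind.
#' @return Non-negative integer Hamming distance.
#' @examples
#' mismatch_count("GATAAT", "TATAAT")  # 1
#' @export
mismatch_count <- function(site, consensus = NULL) {
  seq <- if (inherits(site, "promoter_part")) site$sequence else toupper(site)
  if (is.null(consensus)) {
    if (!inherits(site, "promoter_part"))
      stop("'consensus' is required when 'site' is a plain sequence")
    consensus <- if (site$kind == "minus35") CONSENSUS_MINUS35 else CONSENSUS_MINUS10
  }
  consensus <- toupper(consensus)
  if (nchar(seq) != nchar(consensus))
    stop("sequence and consensus lengths differ (", nchar(seq), " vs ",
         nchar(consensus), ")")
  sum(strsplit(seq, "")[[1]] != strsplit(consensus, "")[[1]])
}

#' Substitute a single base in a promoter part
#'
#' Returns a new part with one base replaced; the label gains a `*` suffix to
#' mark the engineered variant (e.g. `d` TTTACA -> `d*` TTTACT).
#'
#' @param site A [promoter_part()].
#' @param position 0-based index in 0..5 (promoter coordinates are 0-based).
#' @param base Replacement base, one of A, C, G, T.
#' @return A new `promoter_part`.
#' @export
substitute_base <- function(site, position, base) {
  stopifnot(inherits(site, "promoter_part"))
  if (!is.numeric(position) || length(position) != 1L ||
      position < 0 || position > 5 || position != round(position))
    stop("'position' must be an integer in [0, 5]")
  base <- toupper(base)
  if (!is.character(base) || length(base) != 1L || !base %in% c("A", "C", "G", "T"))
    stop("'base' must be one of A, C, G, T")
  s <- strsplit(site$sequence, "")[[1]]
  s[position + 1L] <- base
  promoter_part(paste0(site$label, "*"), site$kind, paste(s, collapse = ""))
}

# full variant sequence for export: activator operator, -35, 17-bp spacer
# (repressor operator padded with N), -10, then reporter context placeholder
variant_sequence <- function(minus35_seq, minus10_seq, architecture) {
  pad <- function(seq, width) {
    if (is.na(seq) || !nzchar(seq)) return(strrep("N", width))
    seq <- toupper(seq)
    if (nchar(seq) >= width) substr(seq, 1L, width)
    else paste0(seq, strrep("N", width - nchar(seq)))
  }
  act <- pad(architecture$activator_operator$sequence, 18L)
  spacer <- if (length(architecture$spacer_operators))
    pad(architecture$spacer_operators[[1L]]$sequence, 17L)
  else strrep("N", 17L)
  paste0(act, minus35_seq, spacer, minus10_seq, "NNNNNN")
}

#' Export a promoter library as multi-FASTA
#'
#' One record per variant; the header is the variant id and the sequence the
#' concatenated architecture elements with `N` placeholder spacers.
#'
#' @param library A `promoter_library`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
export_fasta <- function(library, path) {
  stopifnot(inherits(library, "promoter_library"))
  arch <- attr(library, "architecture")
  seqs <- vapply(seq_len(nrow(library)), function(i)
    variant_sequence(library$minus35_seq[i], library$minus10_seq[i], arch), "")
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- library$id
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Read promoter parts from a CSV definition file
#'
#' Expects columns `label`, `kind`, `sequence`; lines starting with `#` are
#' comments. Two packaged files, `minus35_sites.csv` and `minus10_sites.csv`
#' under `inst/extdata`, define the default 6 x 8 library.
#'
#' @param path CSV file path.
#' @param kind Optional filter, `"minus35"` or `"minus10"`.
#' @return List of [promoter_part()]s.
#' @export
parts_from_csv <- function(path, kind = NULL) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("label", "kind", "sequence")
  if (!all(need %in% names(df)))
    stop("part CSV must have columns: ", paste(need, collapse = ", "))
  if (!is.null(kind)) df <- df[df$kind == kind, , drop = FALSE]
  lapply(seq_len(nrow(df)), function(i)
    promoter_part(df$label[i], df$kind[i], df$sequence[i]))
}
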