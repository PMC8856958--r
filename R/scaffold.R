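# Scaffold templates, guide embedding, and expression-construct
# assembly with restriction-site validation.

#' Scaffold template for shRNAmir embedding
#'
#' A template is an ordered alternation of fixed nucleotide blocks and
#' labelled slots. Slots named `sense_i` / `antisense_i` receive the
#' i-th guide's 22-nt strands at embedding time; everything else
#' (hairpin arms, loops, spacers) is fixed sequence. Templates are
#' data, not code: they can be edited or loaded from YAML so alternative
#' arm/loop sequences drop in without code changes.
#'
#' @slot name Template name (`"mirE"` or `"mir17-19b"`).
#' @slot segments A data.frame with columns `type` (`"fixed"` or
#'   `"slot"`) and `value` (DNA for fixed blocks, slot label for slots).
#' @slot nHairpins 1 for mirE, 4 for the polycistron.
#' @export
setClass("ScaffoldTemplate",
  representation(name = "character", segments = "data.frame",
                 nHairpins = "integer"),
  validity = function(object) {
    seg <- object@segments
    if (!all(c("type", "value") %in% names(seg)))
      return("segments needs columns 'type' and 'value'")
    if (!all(seg$type %in% c("fixed", "slot")))
      return("segment type must be 'fixed' or 'slot'")
    slots <- seg$value[seg$type == "slot"]
    if (anyDuplicated(slots))
      return("slot labels must be unique")
    fixed <- seg$value[seg$type == "fixed"]
    if (length(fixed) && any(!grepl("^[ACGT]+$", fixed)))
      return("fixed blocks must be valid DNA")
    ns <- sum(grepl("^sense_", slots))
    na <- sum(grepl("^antisense_", slots))
    if (ns != object@nHairpins || na != object@nHairpins)
      return(sprintf(
        "expected %d sense/antisense slot pairs, found %d/%d",
        object@nHairpins, ns, na))
    TRUE
  })

#' @rdname ScaffoldTemplate-class
#' @param name,segments,nHairpins See slots.
#' @export
scaffoldTemplate <- function(name, segments, nHairpins = 1L) {
  methods::new("ScaffoldTemplate", name = name,
               segments = as.data.frame(segments),
               nHairpins = as.integer(nHairpins))
}

setMethod("show", "ScaffoldTemplate", function(object) {
  seg <- object@segments
  fixedLen <- sum(nchar(seg$value[seg$type == "fixed"]))
  cat("ScaffoldTemplate", object@name, "|", object@nHairpins,
      "hairpin(s),", nrow(seg), "segments,", fixedLen,
      "nt fixed sequence\n")
})

#' Default mirE scaffold template
#'
#' Single-hairpin template using the standard miR-30a-derived mirE
#' context: 5' flanking arm, sense slot, miR-30 loop, antisense slot,
#' 3' flanking arm.
#'
#' @return A [ScaffoldTemplate-class] with one sense/antisense pair.
#' @export
mirETemplate <- function() {
  scaffoldTemplate("mirE", data.frame(
    type = c("fixed", "slot", "fixed", "slot", "fixed"),
    value = c("TGCTGTTGACAGTGAGCG",   # 5' arm (miR-30a context)
              "sense_1",
              "TAGTGAAGCCACAGATGTA",  # miR-30 loop
              "antisense_1",
              "TGCCTACTGCCTCGGA")),   # 3' arm
    nHairpins = 1L)
}

#' Synthetic four-hairpin polycistronic template
#'
#' A stand-in for the mir17-19b-mimicking polycistronic scaffold: four
#' hairpins (sense slot, loop, antisense slot) joined by spacer blocks.
#' The arm, loop and spacer blocks here are synthetic placeholder
#' sequences -- the true mir17-19b context should be supplied via
#' [readScaffoldTemplate()] when available; the assembly logic is
#' independent of the block content.
#'
#' @return A [ScaffoldTemplate-class] with four sense/antisense pairs.
#' @export
mirPSyntheticTemplate <- function() {
  loops <- c("GTGAAGTCACAATCAA", "GTATTAGTTATCTCCA",
             "GTGATAGTCAAATCGT", "GTACCTGCTGAACTGA")
  spacers <- c("CACCGGTCTCGGA", "CTTGGCATTCCGG", "CAGGTACCTTGAA")
  seg <- list(data.frame(type = "fixed", value = "TGCTGTCAGTGAGCG"))
  for (i in 1:4) {
    seg[[length(seg) + 1L]] <- data.frame(
      type = c("slot", "fixed", "slot"),
      value = c(paste0("sense_", i), loops[i], paste0("antisense_", i)))
    if (i < 4L)
      seg[[length(seg) + 1L]] <- data.frame(type = "fixed",
                                            value = spacers[i])
  }
  seg[[length(seg) + 1L]] <- data.frame(type = "fixed",
                                        value = "TGCCTACTGCACTCGGA")
  scaffoldTemplate("mir17-19b", do.call(rbind, seg), nHairpins = 4L)
}

#' Read / write a scaffold template as YAML
#'
#' The YAML layout is `name`, `n_hairpins`, and `segments`: a list of
#' one-key maps, either `fixed: <DNA>` or `slot: <label>`.
#'
#' @param path YAML file path.
#' @return For the reader, a [ScaffoldTemplate-class]; the writer
#'   returns `path` invisibly.
#' @export
readScaffoldTemplate <- function(path) {
  y <- yaml::read_yaml(path)
  seg <- do.call(rbind, lapply(y$segments, function(s) {
    data.frame(type = names(s)[1L], value = as.character(s[[1L]]))
  }))
  scaffoldTemplate(y$name, seg, y$n_hairpins)
}

#' @rdname readScaffoldTemplate
#' @param template A [ScaffoldTemplate-class].
#' @export
writeScaffoldTemplate <- function(template, path) {
  seg <- template@segments
  yaml::write_yaml(list(
    name = template@name,
    n_hairpins = template@nHairpins,
    segments = lapply(seq_len(nrow(seg)), function(i)
      setNames(list(seg$value[i]), seg$type[i]))), path)
  invisible(path)
}

# Substitute guide strands into a template's slots. guides: DataFrame /
# data.frame with sense22 and antisense22, row i feeding hairpin i.
.fillTemplate <- function(template, guides) {
  seg <- template@segments
  pieces <- character(nrow(seg))
  for (i in seq_len(nrow(seg))) {
    if (seg$type[i] == "fixed") {
      pieces[i] <- seg$value[i]
    } else {
      m <- regmatches(seg$value[i],
                      regexec("^(sense|antisense)_(\\d+)$", seg$value[i]))[[1L]]
      if (length(m) == 0L)
        stop("unrecognized slot label: ", seg$value[i])
      idx <- as.integer(m[3L])
      col <- if (m[2L] == "sense") "sense22" else "antisense22"
      strand <- guides[[col]][idx]
      if (is.na(strand) || nchar(strand) != 22L)
        stop("slot ", seg$value[i], ": guide strand must be 22 nt")
      pieces[i] <- strand
    }
  }
  paste(pieces, collapse = "")
}

#' Embed one guide into the mirE scaffold
#'
#' Substitutes `sense22` and `antisense22` into the template's single
#' slot pair. The result has length `fixed template length + 44`.
#'
#' @param guide One row of [designGuides()] output (or any list with
#'   `sense22` and `antisense22` strings).
#' @param template A single-hairpin [ScaffoldTemplate-class].
#' @return The embedded scaffold sequence (character).
#' @export
embedMirE <- function(guide, template = mirETemplate()) {
  if (template@nHairpins != 1L)
    stop("embedMirE needs a single-hairpin template")
  g <- list(sense22 = guide$sense22[1L],
            antisense22 = guide$antisense22[1L])
  .fillTemplate(template, g)
}

#' Embed four guides into the polycistronic scaffold
#'
#' Hairpin i receives guide i in the given (rank) order.
#'
#' @param guides Exactly four guides (rows with `sense22` /
#'   `antisense22`).
#' @param template A four-hairpin [ScaffoldTemplate-class].
#' @return The embedded polycistronic insert (character).
#' @export
embedPolycistron <- function(guides, template = mirPSyntheticTemplate()) {
  if (nrow(guides) != template@nHairpins)
    stop("need exactly ", template@nHairpins, " guides, got ",
         nrow(guides))
  .fillTemplate(template, guides)
}

#' Default restriction-site recognition sequences
#'
#' BsrGI, AscI (5' flank) and SalI (3' flank). Overridable wherever
#' used.
#'
#' @return Named character vector of recognition sites.
#' @export
defaultFlankSites <- function() {
  c(BsrGI = "TGTACA", AscI = "GGCGCGCC", SalI = "GTCGAC")
}

#' Annotated expression construct
#'
#' The assembled sequence promoter + ORF + 5' flank (BsrGI, AscI) +
#' 3'-UTR scaffold insert + 3' flank (SalI) + downstream remainder,
#' with a feature table (0-based, half-open coordinates) and the flank
#' site sequences used. Validity requires each flank site to occur
#' exactly once in the full sequence and the insert to lie strictly 3'
#' of the ORF stop codon.
#'
#' @slot promoter Promoter label (e.g. "hSyn").
#' @slot orfName ORF label (e.g. "hM4Di_CFP" or "mCherry").
#' @slot utr3Insert The embedded scaffold sequence.
#' @slot flankSites Named character vector of recognition sequences.
#' @slot fullSequence The concatenated construct.
#' @slot features data.frame: `feature`, `type`, `start`, `end`.
#' @export
setClass("ConstructModel",
  representation(promoter = "character", orfName = "character",
                 utr3Insert = "character", flankSites = "character",
                 fullSequence = "character", features = "data.frame"))

setMethod("show", "ConstructModel", function(object) {
  cat("ConstructModel:", object@promoter, "::", object@orfName,
      "| insert", nchar(object@utr3Insert), "nt | total",
      nchar(object@fullSequence), "nt\n")
  cat("flank sites:",
      paste(names(object@flankSites), object@flankSites,
            sep = "=", collapse = ", "), "\n")
  print(object@features)
})

#' Full assembled sequence of a construct
#' @param construct A [ConstructModel-class].
#' @return Character string.
#' @export
constructSequence <- function(construct) construct@fullSequence

#' Feature table of a construct
#' @param construct A [ConstructModel-class].
#' @return data.frame with 0-based half-open `start`/`end`.
#' @export
constructFeatures <- function(construct) construct@features

#' Assemble an expression construct around a scaffold insert
#'
#' Concatenates promoter, ORF, the 5' flank (BsrGI then AscI sites),
#' the 3'-UTR scaffold insert, the 3' flank (SalI) and any downstream
#' backbone remainder, then validates that every declared flank site
#' occurs exactly once in the final sequence. A site re-created inside
#' the insert (or anywhere else) is an error listing the 0-based match
#' positions, since it would break single-cut cloning.
#'
#' @param insert Embedded scaffold sequence ([embedMirE()] /
#'   [embedPolycistron()] output).
#' @param backbone A list describing the vector: `promoter_name`,
#'   `promoter_seq`, `orf_name`, `orf_seq` (must end in a stop codon),
#'   optional `utr3_remainder` (sequence downstream of SalI).
#' @param flankSites Named recognition sequences; the first two names
#'   flank the 5' end, the last the 3' end.
#' @return A [ConstructModel-class].
#' @export
assembleConstruct <- function(insert, backbone,
                              flankSites = defaultFlankSites()) {
  stopifnot(is.character(insert), length(insert) == 1L,
            length(flankSites) >= 2L)
  .assertDna(insert, "insert")
  orf <- backbone$orf_seq
  if (!(substring(orf, nchar(orf) - 2L) %in% c("TAA", "TAG", "TGA")))
    stop("ORF must end in a stop codon")
  n5 <- length(flankSites) - 1L
  flank5 <- paste(flankSites[seq_len(n5)], collapse = "")
  flank3 <- unname(flankSites[length(flankSites)])
  remainder <- if (is.null(backbone$utr3_remainder)) ""
               else backbone$utr3_remainder

  parts <- c(promoter = backbone$promoter_seq, ORF = orf,
             flank5 = flank5, insert = insert, flank3 = flank3,
             remainder = remainder)
  full <- paste(parts, collapse = "")

  # each declared site must occur exactly once in the final sequence
  for (nm in names(flankSites)) {
    pos <- gregexpr(flankSites[[nm]], full, fixed = TRUE)[[1L]]
    pos <- pos[pos > 0L]
    if (length(pos) != 1L)
      stop("restriction site ", nm, " (", flankSites[[nm]], ") occurs ",
           length(pos), " times at 0-based positions [",
           paste(pos - 1L, collapse = ", "),
           "]; each flank site must be unique in the construct")
  }

  ends <- cumsum(nchar(parts))
  starts <- ends - nchar(parts)
  feat <- data.frame(
    feature = c(backbone$promoter_name, backbone$orf_name,
                names(flankSites)[seq_len(n5)], "scaffold_insert",
                names(flankSites)[length(flankSites)]),
    type = c("promoter", "ORF", rep("restriction_site", n5),
             "scaffold", "restriction_site"),
    start = c(starts[["promoter"]], starts[["ORF"]],
              starts[["flank5"]] + c(0L, cumsum(
                nchar(flankSites[seq_len(n5)]))[-n5]),
              starts[["insert"]], starts[["flank3"]]),
    stringsAsFactors = FALSE)
  feat$end <- feat$start + c(nchar(backbone$promoter_seq), nchar(orf),
                             nchar(flankSites[seq_len(n5)]),
                             nchar(insert),
                             nchar(flank3))
  # insert must sit strictly 3' of the ORF stop codon
  stopifnot(starts[["insert"]] >= ends[["ORF"]])

  methods::new("ConstructModel",
               promoter = backbone$promoter_name,
               orfName = backbone$orf_name,
               utr3Insert = insert, flankSites = flankSites,
               fullSequence = full, features = feat)
}

#' Write a construct as an annotated flat file
#'
#' GenBank-style feature lines (1-based inclusive locations, as in
#' flat-file convention) followed by the sequence in 60-nt rows.
#'
#' @param construct A [ConstructModel-class].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeConstructFlat <- function(construct, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("LOCUS  %s_%s  %d bp DNA", construct@promoter,
                     construct@orfName,
                     nchar(construct@fullSequence)), con)
  writeLines("FEATURES", con)
  f <- construct@features
  for (i in seq_len(nrow(f)))
    writeLines(sprintf("  %-18s %-10s %d..%d", f$feature[i], f$type[i],
                       f$start[i] + 1L, f$end[i]), con)
  writeLines("ORIGIN", con)
  s <- construct@fullSequence
  idx <- seq(1L, nchar(s), by = 60L)
  writeLines(substring(s, idx, pmin(idx + 59L, nchar(s))), con)
  invisible(path)
}
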