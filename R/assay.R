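#' Reverse complement of a DNA sequence
#'
#' @param seq A single character string over the alphabet A/C/G/T
#'   (5'->3'). Lower case is accepted and upper-cased.
#' @return The reverse complement, 5'->3', upper case.
#' @examples
#' reverse_complement("ATGC")
#' @export
reverse_complement <- function(seq) {
  seq <- check_dna(seq)
  paste(rev(strsplit(chartr("ACGT", "TGCA", seq), "")[[1]]), collapse = "")
}

check_dna <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq)) {
    stop("`seq` must be a single DNA string", call. = FALSE)
  }
  seq <- toupper(seq)
  if (nchar(seq) == 0L || grepl("[^ACGT]", seq)) {
    stop("invalid DNA sequence: must be non-empty over {A,C,G,T}", call. = FALSE)
  }
  seq
}

#' Count mismatching positions between two equal-length DNA strings
#'
#' @param a,b DNA strings of equal length.
#' @return Integer number of positions at which `a` and `b` differ.
#' @export
mismatch_count <- function(a, b) {
  a <- check_dna(a)
  b <- check_dna(b)
  if (nchar(a) != nchar(b)) {
    stop("sequences must have equal length (", nchar(a), " vs ", nchar(b), ")",
         call. = FALSE)
  }
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Construct a genomic single-nucleotide variant record
#'
#' Coordinates are 1-based, assembly GRCh37 throughout.
#'
#' @param chrom Chromosome name.
#' @param pos 1-based position.
#' @param ref,alt Single reference/alternative bases; must differ.
#' @param label Short label used to name genotypes (e.g. "M1").
#' @return A one-row data.frame with columns chrom, pos, ref, alt, label.
#' @export
genomic_variant <- function(chrom, pos, ref, alt, label) {
  stopifnot(is.numeric(pos), pos > 0)
  ref <- check_dna(ref); alt <- check_dna(alt)
  if (nchar(ref) != 1L || nchar(alt) != 1L) stop("ref/alt must be single bases")
  if (ref == alt) stop("ref and alt must differ")
  data.frame(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
             label = label, stringsAsFactors = FALSE)
}

#' Construct an oligonucleotide record
#'
#' Printed sequences are often grouped in triplets; whitespace is
#' stripped on load.
#'
#' @param name Identifier.
#' @param sequence 5'->3' DNA string.
#' @param role One of "forward_primer", "reverse_primer", "probe".
#' @param fluorophore "HEX", "FAM" or "none". Probes must be labelled;
#'   primers must not be.
#' @param quencher "BHQ1" or "none".
#' @param concentration Concentration in the final reaction, uM (> 0).
#' @return A one-row data.frame.
#' @export
oligo <- function(name, sequence, role,
                  fluorophore = "none", quencher = "none", concentration) {
  role <- match.arg(role, c("forward_primer", "reverse_primer", "probe"))
  fluorophore <- match.arg(fluorophore, c("HEX", "FAM", "none"))
  quencher <- match.arg(quencher, c("BHQ1", "none"))
  sequence <- check_dna(gsub("[[:space:]]", "", sequence))
  if (!is.numeric(concentration) || concentration <= 0) {
    stop("concentration must be > 0 uM")
  }
  if (role == "probe" && fluorophore == "none") {
    stop("probes must carry a fluorophore")
  }
  if (role != "probe" && fluorophore != "none") {
    stop("primers must not carry a fluorophore")
  }
  data.frame(name = name, sequence = sequence, role = role,
             fluorophore = fluorophore, quencher = quencher,
             concentration = concentration, stringsAsFactors = FALSE)
}

#' Construct a duplex screening-assay definition
#'
#' A screening assay carries one primer pair, one HEX-labelled
#' wild-type probe and one or more FAM-labelled mutant probes; any
#' mutant genotype lights the FAM channel, so mutations are detected
#' but not distinguished from one another.
#'
#' @param name Assay identifier.
#' @param oligos A data.frame of oligo records (rbind of [oligo()] rows).
#' @param variants A data.frame of variant records
#'   (rbind of [genomic_variant()] rows), ordered as the single-variant
#'   genotype labels.
#' @param probe_genotype Named character vector mapping probe name ->
#'   genotype label ("WT" plus mutant labels such as "M1", "M2", "M1M2").
#' @param amplicon_length Amplicon length in bp.
#' @param probe_region_start 1-based genomic start of the probe-binding
#'   region on the sense strand (probes are written sense-strand
#'   oriented: they hybridise to the antisense strand).
#' @return An object of class `assay_definition`.
#' @export
assay_definition <- function(name, oligos, variants, probe_genotype,
                             amplicon_length, probe_region_start) {
  stopifnot(is.data.frame(oligos), is.data.frame(variants))
  if (sum(oligos$role == "forward_primer") != 1L ||
      sum(oligos$role == "reverse_primer") != 1L) {
    stop("assay must contain exactly one forward and one reverse primer")
  }
  if (sum(oligos$fluorophore == "HEX") != 1L) {
    stop("assay must contain exactly one HEX (wild-type) probe")
  }
  if (sum(oligos$fluorophore == "FAM") < 1L) {
    stop("assay must contain at least one FAM (mutant) probe")
  }
  primer_len <- sum(nchar(oligos$sequence[oligos$role != "probe"]))
  if (amplicon_length <= primer_len) {
    stop("amplicon_length must exceed the summed primer lengths")
  }
  probes <- oligos[oligos$role == "probe", , drop = FALSE]
  if (!setequal(names(probe_genotype), probes$name)) {
    stop("probe_genotype must name every probe exactly once")
  }
  structure(
    list(name = name, oligos = oligos, variants = variants,
         genotypes = c("WT", setdiff(unname(probe_genotype), "WT")),
         probe_genotype = probe_genotype,
         amplicon_length = as.integer(amplicon_length),
         probe_region_start = as.integer(probe_region_start),
         wild_type_channel = "HEX", mutant_channel = "FAM"),
    class = "assay_definition")
}

#' @export
print.assay_definition <- function(x, ...) {
  cat("<assay_definition> ", x$name, "\n", sep = "")
  cat("  genotypes: ", paste(x$genotypes, collapse = ", "), "\n", sep = "")
  cat("  amplicon:  ", x$amplicon_length, " bp\n", sep = "")
  print(x$oligos[, c("name", "role", "fluorophore", "concentration")],
        row.names = FALSE)
  invisible(x)
}

#' The GPR126 sixth-intron non-coding mutation screening assay
#'
#' Built-in definition of the duplex screening assay targeting the two
#' recurrent substitutions in the GPR126 (ADGRG6) sixth-intron enhancer,
#' chr6:142,706,206 G>A and chr6:142,706,209 C>T (GRCh37): one primer
#' pair, one HEX wild-type probe and three FAM mutant probes (G/A, C/T,
#' and both). Oligo sequences are stored 5'->3', sense-strand oriented.
#'
#' @return An `assay_definition`.
#' @export
gpr126_assay <- function() {
  oligos <- rbind(
    oligo("GPR126_F", "ATG GGA ATA TTA TAA TTC TAA CTA A", "forward_primer",
          concentration = 0.9),
    oligo("GPR126_R", "CAC CGT ATA AAT GTT CTT G", "reverse_primer",
          concentration = 0.9),
    oligo("GPR126_WT", "TT TGT ATG AAC ATA CAA AGA GCC TC", "probe",
          fluorophore = "HEX", quencher = "BHQ1", concentration = 0.25),
    oligo("GPR126_M1", "TTT GTA TAA ACA TAC AAA GAG CCT C", "probe",
          fluorophore = "FAM", quencher = "BHQ1", concentration = 0.083),
    oligo("GPR126_M2", "TTT GTA TGA ATA TAC AAA GAG CCT C", "probe",
          fluorophore = "FAM", quencher = "BHQ1", concentration = 0.083),
    oligo("GPR126_M1M2", "TTT GTA TAA ATA TAC AAA GAG CCT C", "probe",
          fluorophore = "FAM", quencher = "BHQ1", concentration = 0.083))
  variants <- rbind(
    genomic_variant("chr6", 142706206, "G", "A", "M1"),
    genomic_variant("chr6", 142706209, "C", "T", "M2"))
  assay_definition(
    name = "GPR126", oligos = oligos, variants = variants,
    probe_genotype = c(GPR126_WT = "WT", GPR126_M1 = "M1",
                       GPR126_M2 = "M2", GPR126_M1M2 = "M1M2"),
    amplicon_length = 121L,
    probe_region_start = 142706199L)
}

# genotype label -> variant labels substituted into the wild-type
# probe-region sequence ("M1M2" carries both single variants)
genotype_variant_labels <- function(genotype, variants) {
  if (genotype == "WT") return(character(0))
  labs <- strsplit(genotype, "(?<=\\d)(?=M)", perl = TRUE)[[1]]
  if (!all(labs %in% variants$label)) {
    stop("genotype ", genotype, " has no matching variant records")
  }
  labs
}

#' Sense-strand template sequences over the probe-binding region
#'
#' Builds, for every genotype of the assay, the sense-strand sequence
#' of the probe-binding region: the wild-type probe sequence with the
#' genotype's variant alleles substituted at their genomic offsets.
#'
#' @param assay An `assay_definition`.
#' @return Named character vector, one probe-region sequence per genotype.
#' @export
genotype_templates <- function(assay) {
  stopifnot(inherits(assay, "assay_definition"))
  wt <- assay$oligos$sequence[assay$oligos$fluorophore == "HEX"]
  out <- vapply(assay$genotypes, function(g) {
    tmpl <- strsplit(wt, "")[[1]]
    for (lab in genotype_variant_labels(g, assay$variants)) {
      v <- assay$variants[assay$variants$label == lab, ]
      off <- v$pos - assay$probe_region_start + 1L
      if (off < 1L || off > length(tmpl)) {
        stop("variant ", lab, " falls outside the probe-binding region")
      }
      if (tmpl[off] != v$ref) {
        stop("reference base mismatch for variant ", lab,
             " at probe offset ", off)
      }
      tmpl[off] <- v$alt
    }
    paste(tmpl, collapse = "")
  }, character(1))
  out
}

#' Probe-by-genotype mismatch matrix
#'
#' Counts mismatches between every probe and every genotype's
#' probe-region template. A well-designed screening assay has exactly
#' one perfect-match genotype per probe (zero diagonal under matched
#' ordering) and >= 1 mismatch everywhere else.
#'
#' @param assay An `assay_definition`.
#' @return Integer matrix, rows = probes (ordered by their genotype),
#'   columns = genotypes.
#' @export
discrimination_matrix <- function(assay) {
  stopifnot(inherits(assay, "assay_definition"))
  templates <- genotype_templates(assay)
  probes <- assay$oligos[assay$oligos$role == "probe", , drop = FALSE]
  ord <- match(assay$genotypes, assay$probe_genotype[probes$name])
  probes <- probes[ord[!is.na(ord)], , drop = FALSE]
  m <- outer(seq_len(nrow(probes)), seq_along(templates),
             Vectorize(function(i, j) {
               if (nchar(probes$sequence[i]) != nchar(templates[j])) {
                 stop("probe ", probes$name[i],
                      " is not alignable to the probe-binding region")
               }
               mismatch_count(probes$sequence[i], templates[j])
             }))
  dimnames(m) <- list(probe = probes$name,
                      genotype = names(templates))
  m
}

#' Convert a screening assay to a single-target assay
#'
#' A screening assay detects any covered mutation but cannot tell them
#' apart (all mutant probes share FAM). For genotype-specific analysis,
#' the multiplex is reduced to one mutant probe whose concentration is
#' tripled; primers and the wild-type probe are untouched.
#'
#' @param assay A screening `assay_definition` (>= 2 FAM probes).
#' @param genotype Mutant genotype to retain (e.g. "M1").
#' @return A new `assay_definition` with a single FAM probe at 3x its
#'   screening concentration.
#' @export
to_single_target_assay <- function(assay, genotype) {
  stopifnot(inherits(assay, "assay_definition"))
  fam <- assay$oligos$fluorophore == "FAM"
  if (sum(fam) < 2L) {
    stop("assay is already single-target: no screening probe set to reduce")
  }
  probe_name <- names(assay$probe_genotype)[assay$probe_genotype == genotype]
  if (length(probe_name) != 1L || !fam[match(probe_name, assay$oligos$name)]) {
    stop("no FAM probe for genotype ", genotype)
  }
  keep <- !fam | assay$oligos$name == probe_name
  oligos <- assay$oligos[keep, , drop = FALSE]
  sel <- oligos$name == probe_name
  oligos$concentration[sel] <- 3 * oligos$concentration[sel]
  assay_definition(
    name = paste0(assay$name, "_", genotype),
    oligos = oligos, variants = assay$variants,
    probe_genotype = assay$probe_genotype[names(assay$probe_genotype) %in%
                                            oligos$name],
    amplicon_length = assay$amplicon_length,
    probe_region_start = assay$probe_region_start)
}

#' Validate an assay definition
#'
#' Checks oligo composition, the balance of total FAM probe
#' concentration against the HEX probe concentration (the screening
#' design splits the wild-type probe amount evenly across mutant
#' probes), and, when a sense-strand reference fragment is supplied,
#' locates both primers and computes the amplicon length (forward
#' primer start through the reverse-complemented reverse primer end,
#' inclusive).
#'
#' @param assay An `assay_definition`.
#' @param reference_fragment Optional sense-strand DNA string spanning
#'   the amplicon (e.g. from [read_reference_fasta()]).
#' @param conc_tolerance Allowed |sum(FAM) - HEX| imbalance, uM.
#' @return A list of class `assay_validation` with elements
#'   `oligo_counts`, `fam_total`, `hex_total`, `conc_balanced`, and,
#'   with a reference, `forward_start`, `reverse_end`,
#'   `amplicon_length`, `amplicon_matches_declared`.
#' @export
validate_assay <- function(assay, reference_fragment = NULL,
                           conc_tolerance = 0.005) {
  stopifnot(inherits(assay, "assay_definition"))
  ol <- assay$oligos
  fam_total <- sum(ol$concentration[ol$fluorophore == "FAM"])
  hex_total <- sum(ol$concentration[ol$fluorophore == "HEX"])
  rep <- list(
    assay = assay$name,
    oligo_counts = table(ol$role),
    fam_total = fam_total, hex_total = hex_total,
    conc_balanced = abs(fam_total - hex_total) <= conc_tolerance,
    conc_tolerance = conc_tolerance)
  if (!is.null(reference_fragment)) {
    ref <- check_dna(gsub("[[:space:]]", "", reference_fragment))
    fwd <- ol$sequence[ol$role == "forward_primer"]
    rev_rc <- reverse_complement(ol$sequence[ol$role == "reverse_primer"])
    fpos <- gregexpr(fwd, ref, fixed = TRUE)[[1]]
    rpos <- gregexpr(rev_rc, ref, fixed = TRUE)[[1]]
    if (length(fpos) != 1L || fpos[1] < 0L ||
        length(rpos) != 1L || rpos[1] < 0L) {
      stop("ambiguous priming: each primer must match the reference ",
           "fragment exactly once")
    }
    rep$forward_start <- as.integer(fpos[1])
    rep$reverse_end <- as.integer(rpos[1]) + nchar(rev_rc) - 1L
    rep$amplicon_length <- rep$reverse_end - rep$forward_start + 1L
    rep$amplicon_matches_declared <-
      rep$amplicon_length == assay$amplicon_length
  }
  class(rep) <- "assay_validation"
  rep
}

#' @export
print.assay_validation <- function(x, ...) {
  cat("<assay_validation> ", x$assay, "\n", sep = "")
  cat("  FAM total ", format(x$fam_total), " uM vs HEX ",
      format(x$hex_total), " uM (balanced: ", x$conc_balanced, ")\n", sep = "")
  if (!is.null(x$amplicon_length)) {
    cat("  amplicon ", x$amplicon_length, " bp (declared match: ",
        x$amplicon_matches_declared, ")\n", sep = "")
  }
  invisible(x)
}

#' Read the first sequence of a FASTA file as a plain string
#'
#' @param path Path to an (uncompressed) FASTA file.
#' @return Upper-case DNA string.
#' @export
read_reference_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) < 1L) stop("no sequences in ", path)
  toupper(as.character(seqs[[1]]))
}

#' Write / read an assay definition as JSON
#'
#' @param assay An `assay_definition`.
#' @param path Output / input file path.
#' @return `read_assay_json()` returns an `assay_definition`;
#'   `write_assay_json()` returns `path` invisibly.
#' @export
write_assay_json <- function(assay, path) {
  stopifnot(inherits(assay, "assay_definition"))
  jsonlite::write_json(
    list(name = assay$name, oligos = assay$oligos, variants = assay$variants,
         probe_genotype = as.list(assay$probe_genotype),
         amplicon_length = assay$amplicon_length,
         probe_region_start = assay$probe_region_start),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_assay_json
#' @export
read_assay_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  assay_definition(
    name = x$name, oligos = x$oligos, variants = x$variants,
    probe_genotype = unlist(x$probe_genotype),
    amplicon_length = x$amplicon_length,
    probe_region_start = x$probe_region_start)
}
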