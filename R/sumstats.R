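#' @include AllClasses.R
NULL

#' Construct a GwasSumstats object
#'
#' Builds and validates a per-variant summary-statistics container from a
#' data.frame. Alleles are upper-cased; columns not part of the canonical set
#' are dropped; missing optional columns (\code{chrom}, \code{pos},
#' \code{pval}, \code{n}) are filled with \code{NA}.
#'
#' When \code{checkPvals = TRUE}, each reported p-value is compared with the
#' two-sided normal p implied by \code{|beta/se|}; disagreement beyond a
#' factor of 2 raises a warning (never an error), since rounding of beta and
#' se in public summary files routinely perturbs small p-values.
#'
#' @param variants data.frame with at least \code{rsid},
#'   \code{effect_allele}, \code{other_allele}, \code{eaf}, \code{beta},
#'   \code{se}.
#' @param trait trait label.
#' @param scale one of \code{"linear"}, \code{"log_odds"},
#'   \code{"inverse_normal"}.
#' @param checkPvals run the loose p-value consistency check.
#' @return a [GwasSumstats-class] object.
#' @examples
#' gwasSumstats(data.frame(rsid = "rs1", effect_allele = "a",
#'                         other_allele = "g", eaf = 0.2, beta = 0.1,
#'                         se = 0.02), trait = "exposure")
#' @export
gwasSumstats <- function(variants, trait = "trait", scale = "linear",
                         checkPvals = TRUE) {
  mandatory <- c("rsid", "effect_allele", "other_allele", "eaf", "beta", "se")
  missing_cols <- setdiff(mandatory, names(variants))
  if (length(missing_cols) > 0)
    stop("missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  v <- data.frame(
    rsid = as.character(variants$rsid),
    chrom = if ("chrom" %in% names(variants))
      as.character(variants$chrom) else NA_character_,
    pos = if ("pos" %in% names(variants))
      as.integer(variants$pos) else NA_integer_,
    effect_allele = toupper(as.character(variants$effect_allele)),
    other_allele = toupper(as.character(variants$other_allele)),
    eaf = as.numeric(variants$eaf),
    beta = as.numeric(variants$beta),
    se = as.numeric(variants$se),
    pval = if ("pval" %in% names(variants))
      as.numeric(variants$pval) else NA_real_,
    n = if ("n" %in% names(variants)) as.numeric(variants$n) else NA_real_,
    stringsAsFactors = FALSE)
  obj <- new("GwasSumstats", variants = v, trait = as.character(trait),
             scale = scale)
  if (checkPvals && nrow(v) > 0) {
    has_p <- !is.na(v$pval)
    if (any(has_p)) {
      implied <- 2 * stats::pnorm(-abs(v$beta[has_p] / v$se[has_p]))
      off <- v$pval[has_p] > pmin(1, 2 * implied) |
             v$pval[has_p] < implied / 2
      if (any(off))
        warning("reported p-value inconsistent with |beta/se| ",
                "(beyond factor 2) for: ",
                paste(v$rsid[has_p][off], collapse = ", "))
    }
  }
  obj
}

#' Construct an InstrumentSet
#'
#' @param variants data.frame of exposure instruments (see [gwasSumstats()]),
#'   or a [GwasSumstats-class] object.
#' @param r2Total total proportion of exposure variance explained by the
#'   instruments, in (0, 1).
#' @param trait,scale,checkPvals passed to [gwasSumstats()] when
#'   \code{variants} is a data.frame.
#' @return an [InstrumentSet-class] object.
#' @export
instrumentSet <- function(variants, r2Total, trait = "exposure",
                          scale = "inverse_normal", checkPvals = TRUE) {
  ss <- if (is(variants, "GwasSumstats")) variants
        else gwasSumstats(variants, trait = trait, scale = scale,
                          checkPvals = checkPvals)
  new("InstrumentSet", variants = ss@variants, trait = ss@trait,
      scale = ss@scale, r2Total = as.numeric(r2Total))
}

#' Construct a StudyMeta
#'
#' @param nCases,nControls positive integer case/control counts.
#' @return a [StudyMeta-class] object.
#' @examples
#' studyMeta(11802, 137950)  # caseFraction() ~ 0.0788
#' @export
studyMeta <- function(nCases, nControls) {
  new("StudyMeta", nCases = as.numeric(nCases),
      nControls = as.numeric(nControls))
}

#' Canonical summary-statistics column dialect
#'
#' The canonical file format is tab-separated with a header row and columns
#' \code{rsid, chr, pos, ea, oa, eaf, beta, se, p, n}. A dialect is a named
#' character vector mapping internal field names to file column names;
#' alternative layouts are described by supplying a different mapping.
#'
#' @return named character vector (internal field -> file column).
#' @export
canonicalDialect <- function() {
  c(rsid = "rsid", chrom = "chr", pos = "pos", effect_allele = "ea",
    other_allele = "oa", eaf = "eaf", beta = "beta", se = "se",
    pval = "p", n = "n")
}

#' Read a column-dialect mapping from a key=value config file
#'
#' Each non-blank, non-comment line is \code{field = column}; fields not
#' mentioned keep their canonical column name.
#'
#' @param path config file path.
#' @return named character vector usable as the \code{dialect} argument of
#'   [readSumstats()].
#' @export
readDialect <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  d <- canonicalDialect()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2)
      stop("malformed dialect line: '", ln, "'")
    key <- trimws(kv[1])
    if (!key %in% names(d))
      stop("unknown dialect field: '", key, "'")
    d[key] <- trimws(kv[2])
  }
  d
}

#' Read GWAS summary statistics from delimited text
#'
#' Reads a header-bearing delimited file into a [GwasSumstats-class] object.
#' Rows violating the type/range invariants (alleles outside A/C/G/T,
#' \code{eaf} outside (0, 1), non-positive \code{se}, p outside (0, 1], or a
#' non-positive \code{n}) are rejected, not silently fixed; the rejection
#' report (row number, field, message) is attached as the \code{"rejected"}
#' attribute and retrievable with [rejectedRows()], and optionally written as
#' a TSV.
#'
#' @param path input file.
#' @param dialect named mapping from internal fields to file column names;
#'   see [canonicalDialect()]. Fields \code{rsid}, \code{effect_allele},
#'   \code{other_allele}, \code{eaf}, \code{beta}, \code{se} are mandatory in
#'   the file; the others are optional.
#' @param trait,scale metadata for the resulting object.
#' @param sep field separator (tab for the canonical dialect).
#' @param rejectPath optional path to write the rejection report TSV.
#' @return a [GwasSumstats-class] object.
#' @export
readSumstats <- function(path, dialect = canonicalDialect(),
                         trait = "trait", scale = "linear", sep = "\t",
                         rejectPath = NULL) {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE)
  if (nrow(raw) == 0)
    stop("empty input: '", path, "' contains no data rows")
  mandatory <- c("rsid", "effect_allele", "other_allele", "eaf", "beta", "se")
  have <- names(dialect)[dialect %in% names(raw)]
  missing_cols <- setdiff(mandatory, have)
  if (length(missing_cols) > 0)
    stop("configuration error: file lacks mapped column(s) for: ",
         paste(missing_cols, collapse = ", "))
  pick <- function(field) {
    col <- dialect[[field]]
    if (!is.null(col) && col %in% names(raw)) raw[[col]] else
      rep(NA_character_, nrow(raw))
  }
  d <- data.frame(
    rsid = pick("rsid"), chrom = pick("chrom"),
    pos = suppressWarnings(as.integer(pick("pos"))),
    effect_allele = toupper(pick("effect_allele")),
    other_allele = toupper(pick("other_allele")),
    eaf = suppressWarnings(as.numeric(pick("eaf"))),
    beta = suppressWarnings(as.numeric(pick("beta"))),
    se = suppressWarnings(as.numeric(pick("se"))),
    pval = suppressWarnings(as.numeric(pick("pval"))),
    n = suppressWarnings(as.numeric(pick("n"))),
    stringsAsFactors = FALSE)

  reject <- function(rows, field, msg) {
    if (!any(rows)) return(NULL)
    data.frame(row = which(rows), rsid = d$rsid[rows], field = field,
               message = msg, stringsAsFactors = FALSE)
  }
  reports <- rbind(
    reject(!d$effect_allele %in% .VALID_ALLELES, "effect_allele",
           "allele not one of A/C/G/T"),
    reject(!d$other_allele %in% .VALID_ALLELES, "other_allele",
           "allele not one of A/C/G/T"),
    reject(d$effect_allele %in% .VALID_ALLELES &
           d$effect_allele == d$other_allele, "other_allele",
           "effect and other allele identical"),
    reject(is.na(d$eaf) | d$eaf <= 0 | d$eaf >= 1, "eaf",
           "eaf not strictly in (0, 1)"),
    reject(is.na(d$beta), "beta", "beta missing or non-numeric"),
    reject(is.na(d$se) | d$se <= 0, "se", "se not positive"),
    reject(!is.na(d$pval) & (d$pval <= 0 | d$pval > 1), "pval",
           "p-value not in (0, 1]"),
    reject(!is.na(d$n) & d$n <= 0, "n", "n not positive"))
  bad_rows <- if (is.null(reports)) integer(0) else unique(reports$row)
  if (length(bad_rows) > 0) {
    warning(length(bad_rows), " row(s) rejected; see rejection report")
    d <- d[-bad_rows, , drop = FALSE]
  }
  if (!is.null(rejectPath)) {
    rep_out <- if (is.null(reports))
      data.frame(row = integer(0), rsid = character(0), field = character(0),
                 message = character(0)) else reports
    utils::write.table(rep_out, rejectPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  obj <- gwasSumstats(d, trait = trait, scale = scale, checkPvals = FALSE)
  attr(obj, "rejected") <- reports
  obj
}

#' Per-row rejection report of a read
#'
#' @param x a [GwasSumstats-class] returned by [readSumstats()].
#' @return data.frame of rejected rows (row, rsid, field, message), or NULL
#'   if nothing was rejected.
#' @export
rejectedRows <- function(x) attr(x, "rejected")

#' Write summary statistics in the canonical TSV dialect
#'
#' Canonical formatting: tab-separated, header
#' \code{rsid chr pos ea oa eaf beta se p n}, numbers via \code{format()}
#' with 15 significant digits, missing values as \code{NA}. Writing, reading
#' back and writing again is byte-identical.
#'
#' @param x a [GwasSumstats-class] object.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeSumstats <- function(x, path) {
  v <- variants(x)
  num <- function(z) ifelse(is.na(z), "NA", format(z, digits = 15,
                                                   scientific = FALSE,
                                                   trim = TRUE))
  out <- data.frame(rsid = v$rsid,
                    chr = ifelse(is.na(v$chrom), "NA", v$chrom),
                    pos = ifelse(is.na(v$pos), "NA", as.character(v$pos)),
                    ea = v$effect_allele, oa = v$other_allele,
                    eaf = num(v$eaf), beta = num(v$beta), se = num(v$se),
                    p = num(v$pval), n = num(v$n),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
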