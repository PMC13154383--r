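#' @importFrom methods is
#' @importFrom stats aggregate as.dist cmdscale cor cutree dist hclust
#'   isoreg lm median pnorm rlnorm rnbinom rnorm runif sd setNames var
#' @importFrom utils combn read.delim write.table head
#' @importFrom graphics abline lines par
NULL

## ---------------------------------------------------------------------------
## Logging
## ---------------------------------------------------------------------------

#' Emit a structured pipeline log line
#'
#' One line per stage with input/output record counts, so that filter
#' behaviour can be audited after a run. Controlled by
#' `options(halovir.log_level = "info" | "quiet")`.
#'
#' @param stage character scalar naming the pipeline stage.
#' @param ... named counts or short messages to append.
#' @return invisibly, the formatted line.
#' @keywords internal
hv_log <- function(stage, ...) {
  lvl <- getOption("halovir.log_level", "info")
  kv <- list(...)
  txt <- if (length(kv)) {
    paste(vapply(seq_along(kv), function(i) {
      paste0(names(kv)[i], "=", paste(format(kv[[i]]), collapse = ","))
    }, character(1)), collapse = " ")
  } else ""
  line <- sprintf("[halovir:%s] %s", stage, txt)
  if (!identical(lvl, "quiet")) message(line)
  invisible(line)
}

## ---------------------------------------------------------------------------
## Run configuration
## ---------------------------------------------------------------------------

hv_default_config <- function() {
  list(
    min_length   = 10000L,  # keep contigs strictly longer than this (bp)
    min_tools    = 2L,      # predictors that must agree
    ani          = 0.95,    # vOTU clustering identity threshold
    af           = 0.85,    # aligned fraction of the shorter sequence
    breadth      = 0.75,    # detection requires breadth strictly above this
    majority     = 0.5,     # taxonomy requires strictly more than this
    k_min        = 1L,
    k_max        = 20L,
    permutations = 9999L,
    seed         = 1L,
    distance     = "clr_euclidean",  # or "bray"
    kmer         = 15L,     # ANI seed length
    min_block    = 100L,    # minimum alignment block (bp)
    pool_genes   = FALSE,   # taxonomy votes: representative only (FALSE) or all members
    trim_delim   = "||",    # predictor trim-suffix delimiter
    nmds_restarts = 20L
  )
}

hv_config_ranges <- list(
  ani = c(0, 1), af = c(0, 1), breadth = c(0, 1), majority = c(0, 1),
  min_length = c(0, Inf), min_tools = c(1, Inf), k_min = c(1, Inf),
  k_max = c(1, Inf), permutations = c(1, Inf), kmer = c(4, 31),
  min_block = c(1, Inf), nmds_restarts = c(1, Inf)
)

#' Load and validate a run configuration
#'
#' Reads an optional DCF file (`key: value` lines) of overrides on top of the
#' package defaults (minimum contig length 10,000 bp; at least 2 predictors;
#' 95% ANI / 85% aligned fraction; breadth 0.75; strict 50% taxonomy
#' majority; k searched over 1..20; 9,999 permutations). Unknown keys are
#' rejected; out-of-range thresholds raise errors; all effective values are
#' logged at load.
#'
#' @param path path to a DCF config file, or `NULL` for pure defaults.
#' @param overrides named list applied after the file (programmatic use).
#' @return a named list of validated configuration values.
#' @export
#' @examples
#' cfg <- load_config()          # full default set
#' cfg$breadth
load_config <- function(path = NULL, overrides = list()) {
  cfg <- hv_default_config()
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    m <- read.dcf(path)
    if (nrow(m) > 0) user <- as.list(m[1, ])
  }
  user <- c(user, overrides)
  for (k in names(user)) {
    if (!k %in% names(cfg)) stop("unknown configuration key: ", k)
    v <- user[[k]]
    if (is.character(v) && !is.character(cfg[[k]])) v <- as.numeric(v)
    if (is.numeric(cfg[[k]]) || is.integer(cfg[[k]])) {
      if (!is.finite(v)) stop("non-numeric value for key ", k)
      rng <- hv_config_ranges[[k]]
      if (!is.null(rng) && (v < rng[1] || v > rng[2])) {
        stop("configuration value out of range [", rng[1], ", ", rng[2],
             "] for key ", k, ": ", v)
      }
      if (is.integer(cfg[[k]])) v <- as.integer(v)
    }
    cfg[[k]] <- v
  }
  if (cfg$k_min > cfg$k_max) stop("k_min exceeds k_max")
  if (!cfg$distance %in% c("clr_euclidean", "bray")) {
    stop("distance must be 'clr_euclidean' or 'bray'")
  }
  hv_log("config", defaults = sum(!names(cfg) %in% names(user)),
         overridden = length(user))
  cfg
}

## ---------------------------------------------------------------------------
## FASTA
## ---------------------------------------------------------------------------

#' Read a FASTA file of contigs
#'
#' @param path FASTA file path.
#' @return named character vector of sequences (names = contig ids). An empty
#'   file yields an empty vector; duplicated ids are an error naming the id.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (file.size(path) == 0) return(setNames(character(0), character(0)))
  ss <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate FASTA id: ", dup[1])
  setNames(as.character(ss), ids)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line-wrap width (fixed on write so output is reproducible).
#' @return invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(unname(seqs))
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Tab-separated tables with named schemas
## ---------------------------------------------------------------------------

## required column -> type ("c" character, "i" integer, "d" double, "D" date)
hv_schemas <- list(
  metadata = c(site = "c", date = "D", season = "c", temp_C = "d",
               do_mg_per_L = "d", salinity_ppt = "d", pH = "d", nh4_uM = "d",
               no3_uM = "d", no2_uM = "d", autofluor_cells_per_mL = "d"),
  predictor_calls = c(contig_id = "c", predictor = "c", called_length_bp = "i"),
  read_counts = c(sample_id = "c", contig_id = "c", reads = "i"),
  coverage = c(sample_id = "c", contig_id = "c", start = "i", end = "i"),
  gene_taxonomy = c(contig_id = "c", gene_id = "c", realm = "c", kingdom = "c",
                    phylum = "c", class = "c", order = "c", family = "c",
                    environment = "c"),
  amg = c(votu_id = "c", contig_id = "c", kegg_pathway = "c"),
  host_predictions = c(votu_id = "c", host_genome = "c", score = "d"),
  mags = c(mag_id = "c", completion = "d", contamination = "d", domain = "c",
           phylum = "c", class = "c", order = "c"),
  contig_origin = c(contig_id = "c", sample_id = "c", site = "c", date = "D",
                    fraction = "c")
)

#' Read a typed tab-separated table against a named schema
#'
#' All pipeline tables are TSV, UTF-8, one header row, missing values as the
#' empty string, ISO-8601 dates, 0-based half-open coverage coordinates.
#' Unknown extra columns are preserved with a warning; missing required
#' columns are a schema error listing all missing names; unparseable cells
#' report their row number.
#'
#' @param path TSV path.
#' @param schema_name one of `names(halovir:::hv_schemas)`.
#' @return a data.frame with typed columns.
#' @export
read_table <- function(path, schema_name) {
  schema <- hv_schemas[[schema_name]]
  if (is.null(schema)) stop("unknown schema: ", schema_name)
  if (!file.exists(path)) stop("table not found: ", path)
  df <- read.delim(path, sep = "\t", header = TRUE, colClasses = "character",
                   check.names = FALSE, comment.char = "#",
                   na.strings = character(0))
  missing <- setdiff(names(schema), names(df))
  if (length(missing)) {
    stop("schema '", schema_name, "': missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(df), names(schema))
  if (length(extra)) {
    warning("schema '", schema_name, "': preserving unknown column(s): ",
            paste(extra, collapse = ", "))
  }
  for (col in names(schema)) {
    ty <- schema[[col]]
    x <- df[[col]]
    x[x == ""] <- NA
    if (ty == "c") { df[[col]] <- x; next }
    parsed <- switch(ty,
      i = suppressWarnings(as.integer(x)),
      d = suppressWarnings(as.numeric(x)),
      D = as.Date(x, format = "%Y-%m-%d"))
    bad <- which(!is.na(x) & is.na(parsed))
    if (length(bad)) {
      stop("schema '", schema_name, "', column '", col,
           "': unparseable value at data row ", bad[1], ": '", x[bad[1]], "'")
    }
    df[[col]] <- parsed
  }
  df
}

#' Write a table as TSV
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param header_comments optional character vector written as leading
#'   `#`-prefixed lines (used by the generator to record distribution means).
#' @return invisibly, `path`.
#' @export
write_tsv <- function(df, path, header_comments = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(header_comments)) {
    writeLines(paste0("# ", header_comments), con)
  }
  df2 <- df
  for (j in seq_along(df2)) {
    if (inherits(df2[[j]], "Date")) df2[[j]] <- format(df2[[j]], "%Y-%m-%d")
  }
  write.table(df2, con, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Strip the predictor trim suffix from a contig id
#'
#' Provirus-trimming predictors emit variants named
#' `<base><delim><coords>`; the base name identifies the source contig.
#'
#' @param contig_id character vector of ids.
#' @param delim trim-suffix delimiter (default `"||"`).
#' @return character vector of base names.
#' @export
base_name <- function(contig_id, delim = "||") {
  vapply(strsplit(contig_id, delim, fixed = TRUE),
         function(p) p[[1]], character(1))
}

#' Bundled two-site abiotic monitoring table
#'
#' The eight-date, two-site table of abiotic conditions (temperature,
#' dissolved oxygen, salinity, pH, ammonium, nitrate, nitrite,
#' auto-fluorescing cell counts) for the Los Olmos Creek (LOC) and Riviera
#' Beach (RB) sites of a hypersaline estuary, used by the worked examples and
#' by [site_summary()].
#'
#' @return a data.frame in the `metadata` schema (16 rows).
#' @export
#' @examples
#' head(abiotic_conditions())
abiotic_conditions <- function() {
  read_table(system.file("extdata", "abiotic_conditions.tsv",
                         package = "halovir", mustWork = TRUE),
             "metadata")
}
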