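#' Canonical taxon registry for the vaginal microbiome
#'
#' A taxon registry holds the canonical nomenclature used by every other
#' stage of the pipeline: canonical taxon names with their working rank,
#' membership in one of five disjoint functional groups, and a synonym map
#' that folds raw input labels (species names, abbreviations, renamed taxa)
#' onto canonical names.
#'
#' The five functional groups are:
#' \describe{
#'   \item{LACTOBACILLUS}{the four canonical species used to name CST
#'     I/II/III/V (\emph{L. crispatus}, \emph{L. gasseri}, \emph{L. iners},
#'     \emph{L. jensenii}) plus other vaginal lactobacilli kept at species
#'     rank.}
#'   \item{GARDNERELLA}{\emph{Gardnerella vaginalis}.}
#'   \item{PREVOTELLA}{the \emph{Prevotella} genus-level taxa.}
#'   \item{THPP}{"taxa with high pathogenic potential": facultative
#'     anaerobes and genital pathogens such as \emph{Streptococcus},
#'     \emph{Staphylococcus}, \emph{Enterococcus}, \emph{Escherichia-Shigella},
#'     \emph{Mycoplasma} and \emph{Ureaplasma}.}
#'   \item{OTHER}{the implicit complement (heterogeneous anaerobes, rare
#'     taxa, unassigned reads).}
#' }
#'
#' Groups are disjoint: every canonical name belongs to exactly one group.
#'
#' @return An object of class \code{taxon_registry}: a list with elements
#'   \code{taxa} (data frame with columns \code{canonical}, \code{rank},
#'   \code{group}) and \code{synonyms} (named character vector, normalized
#'   alias -> canonical name).
#'
#' @examples
#' reg <- default_registry()
#' group_of("Mycoplasma hominis", reg)   # "THPP"
#' canonicalize("Shuttleworthia", reg)$canonical
#' @export
default_registry <- function() {
  species <- function(x) data.frame(canonical = x, rank = "species")
  genus   <- function(x) data.frame(canonical = x, rank = "genus")
  grp     <- function(x) data.frame(canonical = x, rank = "group")

  lacto <- rbind(
    species(c("Lactobacillus crispatus", "Lactobacillus gasseri",
              "Lactobacillus iners", "Lactobacillus jensenii",
              "Lactobacillus equi", "Lactobacillus mucosae",
              "Lactobacillus murinus", "Lactobacillus salivarius")),
    genus("Lactobacillus"))
  lacto$group <- "LACTOBACILLUS"

  gard <- species("Gardnerella vaginalis")
  gard$group <- "GARDNERELLA"

  prev <- genus(c("Prevotella", "Prevotella 6"))
  prev$group <- "PREVOTELLA"

  thpp <- genus(c("Campylobacter", "Chlamydia", "Enterococcus",
                  "Escherichia-Shigella", "Haemophilus", "Mycoplasma",
                  "Neisseria", "Peptostreptococcus", "Staphylococcus",
                  "Streptococcus", "Ureaplasma"))
  thpp$group <- "THPP"

  other <- rbind(
    genus(c("Sneathia", "Megasphaera", "Atopobium",
            "Candidatus Lachnocurva vaginae", "Anaerococcus",
            "Corynebacterium", "Veillonella", "Fastidiosipila",
            "Bifidobacterium", "Peptoniphilus", "Dialister",
            "Porphyromonas", "Gemella", "Finegoldia", "Mobiluncus",
            "Parvimonas", "Moryella", "Scardovia", "Ralstonia",
            "Howardella", "Aerococcus", "Acinetobacter", "Fusobacterium",
            "Eggerthella")),
    grp(c("Clostridiales bacterium", "Bacilli")),
    data.frame(canonical = "Unassigned", rank = "unassigned"))
  other$group <- "OTHER"

  taxa <- rbind(lacto, gard, prev, thpp, other)
  rownames(taxa) <- NULL

  syn <- c(
    # renamed taxon: BVAB1 / Shuttleworthia -> Candidatus Lachnocurva vaginae
    "Shuttleworthia"        = "Candidatus Lachnocurva vaginae",
    "Shuttleworthia (BVAB1)" = "Candidatus Lachnocurva vaginae",
    "Shuttleworthia (BVBA1)" = "Candidatus Lachnocurva vaginae",
    "BVAB1"                 = "Candidatus Lachnocurva vaginae",
    "Lachnocurva vaginae"   = "Candidatus Lachnocurva vaginae",
    # Lactobacillus abbreviations
    "L. crispatus" = "Lactobacillus crispatus",
    "L. gasseri"   = "Lactobacillus gasseri",
    "L. iners"     = "Lactobacillus iners",
    "L. jensenii"  = "Lactobacillus jensenii",
    "L. salivarius" = "Lactobacillus salivarius",
    # Gardnerella: the genus is monospecific here
    "Gardnerella"  = "Gardnerella vaginalis",
    "G. vaginalis" = "Gardnerella vaginalis",
    # SILVA-style merged genus
    "Escherichia" = "Escherichia-Shigella",
    "Shigella"    = "Escherichia-Shigella",
    # species folded to their working (genus) rank
    "Prevotella bivia" = "Prevotella", "Prevotella amnii" = "Prevotella",
    "Prevotella denticola" = "Prevotella", "Prevotella buccalis" = "Prevotella",
    "Prevotella disiens" = "Prevotella", "Prevotella ihumnii" = "Prevotella",
    "P. bivia" = "Prevotella",
    "Sneathia amnii" = "Sneathia", "Sneathia sanguinegens" = "Sneathia",
    "Sneathia spp." = "Sneathia",
    "Veillonella montpellierensis" = "Veillonella",
    "Veillonella seminalis" = "Veillonella",
    "Anaerococcus vaginalis" = "Anaerococcus",
    "Anaerococcus lactolyticus" = "Anaerococcus",
    "Anaerococcus prevotii" = "Anaerococcus",
    "Anaerococcus provenciensis" = "Anaerococcus",
    "Bifidobacterium breve" = "Bifidobacterium",
    "Bifidobacterium longum" = "Bifidobacterium",
    "Bifidobacterium bifidum" = "Bifidobacterium",
    "Bifidobacterium dentium" = "Bifidobacterium",
    "Bifidobacterium avesanii" = "Bifidobacterium",
    "B. breve" = "Bifidobacterium",
    "Streptococcus agalactiae" = "Streptococcus",
    "Streptococcus anginosus" = "Streptococcus",
    "Streptococcus salivarius" = "Streptococcus",
    "S. agalactiae" = "Streptococcus",
    "Mycoplasma hominis" = "Mycoplasma", "M. hominis" = "Mycoplasma",
    "Ureaplasma parvum" = "Ureaplasma", "U. parvum" = "Ureaplasma",
    "Chlamydia trachomatis" = "Chlamydia",
    "Neisseria gonorrhoeae" = "Neisseria",
    "Scardovia wiggsiae" = "Scardovia",
    "Atopobium deltae" = "Atopobium", "Atopobium minutum" = "Atopobium",
    "Megasphaera indica" = "Megasphaera",
    "Finegoldia magna" = "Finegoldia",
    "Corynebacterium 1" = "Corynebacterium",
    "Moryella indoligenes" = "Moryella",
    "Mobiluncus curtisii" = "Mobiluncus",
    "Gemella asaccharolytica" = "Gemella",
    "Gemella haemolysans" = "Gemella",
    "Dialister pneumosintes" = "Dialister",
    "Porphyromonas asaccharolytica" = "Porphyromonas",
    "Unassigned bacteria" = "Unassigned",
    "unassigned" = "Unassigned")

  new_taxon_registry(taxa, syn)
}

new_taxon_registry <- function(taxa, synonyms) {
  taxa$canonical <- as.character(taxa$canonical)
  taxa$rank <- as.character(taxa$rank)
  taxa$group <- as.character(taxa$group)
  if (anyDuplicated(taxa$canonical)) {
    stop_vagcst("registry has duplicated canonical names")
  }
  bad_rank <- setdiff(taxa$rank, c("species", "genus", "group", "unassigned"))
  if (length(bad_rank)) {
    stop_vagcst("unknown rank(s) in registry: ", paste(bad_rank, collapse = ", "))
  }
  bad_grp <- setdiff(taxa$group,
                     c("LACTOBACILLUS", "GARDNERELLA", "PREVOTELLA", "THPP",
                       "OTHER"))
  if (length(bad_grp)) {
    stop_vagcst("unknown group(s) in registry: ", paste(bad_grp, collapse = ", "))
  }
  if (length(synonyms)) {
    missing <- setdiff(unname(synonyms), taxa$canonical)
    if (length(missing)) {
      stop_vagcst("synonym target(s) not in registry: ",
                  paste(missing, collapse = ", "))
    }
  }
  structure(list(taxa = taxa, synonyms = synonyms,
                 lookup = build_lookup(taxa, synonyms)),
            class = "taxon_registry")
}

# normalized label -> canonical name map (environment for O(1) lookup)
build_lookup <- function(taxa, synonyms) {
  keys <- c(normalize_label(taxa$canonical), normalize_label(names(synonyms)))
  vals <- c(taxa$canonical, unname(synonyms))
  keep <- !duplicated(keys)  # canonical entries win over synonym collisions
  as.list(stats::setNames(vals[keep], keys[keep]))
}

# case-, whitespace-, underscore- and dash-variant insensitive key
normalize_label <- function(x) {
  x <- gsub("[–—]", "-", x)     # en/em dash -> hyphen
  x <- gsub("[_\\s]+", " ", x, perl = TRUE)
  x <- trimws(x)
  tolower(x)
}

#' Resolve a raw taxon label to its canonical name
#'
#' Matching ignores case, surrounding whitespace, underscore/space
#' differences and en/em-dash variants, and consults the registry's synonym
#' table (so e.g. \code{"Shuttleworthia"} resolves to
#' \code{"Candidatus Lachnocurva vaginae"} and species labels fold to their
#' working rank). Unknown labels pass through unchanged at rank
#' \code{"unassigned"} with a warning.
#'
#' @param label a single non-empty taxon label as it appears in an input table.
#' @param registry a \code{taxon_registry}, e.g. \code{default_registry()}.
#' @param warn warn on unknown labels? Default \code{TRUE}.
#' @return A list with fields \code{raw_label}, \code{canonical},
#'   \code{rank} and \code{group}.
#' @examples
#' canonicalize("Escherichia-Shigella", default_registry())$group  # "THPP"
#' @export
canonicalize <- function(label, registry, warn = TRUE) {
  if (length(label) != 1L || is.na(label) || !nzchar(trimws(label))) {
    stop_vagcst("taxon label must be a single non-empty string")
  }
  canon <- canonical_names(label, registry, warn = warn)
  i <- match(canon, registry$taxa$canonical)
  if (is.na(i)) {
    list(raw_label = label, canonical = canon, rank = "unassigned",
         group = "OTHER")
  } else {
    list(raw_label = label, canonical = canon,
         rank = registry$taxa$rank[i], group = registry$taxa$group[i])
  }
}

# vectorized canonicalization used by table readers; unknown labels pass
# through with their whitespace trimmed
canonical_names <- function(labels, registry, warn = TRUE) {
  keys <- normalize_label(labels)
  found <- keys %in% names(registry$lookup)
  out <- trimws(labels)
  out[found] <- vapply(keys[found], function(k) registry$lookup[[k]], "")
  if (warn && any(!found)) {
    warning("unknown taxon label(s) kept as-is at rank 'unassigned': ",
            paste(unique(labels[!found]), collapse = ", "), call. = FALSE)
  }
  out
}

#' Functional group of a canonical taxon
#'
#' @param name a canonical taxon name (or any label resolvable by
#'   \code{\link{canonicalize}}).
#' @param registry a \code{taxon_registry}.
#' @return One of \code{"LACTOBACILLUS"}, \code{"GARDNERELLA"},
#'   \code{"PREVOTELLA"}, \code{"THPP"}, \code{"OTHER"}. Names in no explicit
#'   group return \code{"OTHER"}.
#' @export
group_of <- function(name, registry) {
  canonicalize(name, registry, warn = FALSE)$group
}

#' Canonical members of a functional group
#'
#' @param group one of the five group names.
#' @param registry a \code{taxon_registry}.
#' @return Character vector of canonical names in that group.
#' @export
group_members <- function(group, registry) {
  group <- match.arg(group, c("LACTOBACILLUS", "GARDNERELLA", "PREVOTELLA",
                              "THPP", "OTHER"))
  registry$taxa$canonical[registry$taxa$group == group]
}

#' Read / write a taxon registry file
#'
#' Plain-text tab-separated format: taxon lines have three fields
#' (\code{canonical_name}, \code{rank}, \code{group}); synonym lines have two
#' fields (\code{alias}, \code{canonical}). Lines starting with \code{#} are
#' comments. Writing then re-reading reproduces an identical registry.
#'
#' @param path file path.
#' @return \code{read_taxon_registry} returns a \code{taxon_registry};
#'   \code{write_taxon_registry} returns \code{path} invisibly.
#' @export
read_taxon_registry <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(!nf %in% c(2L, 3L))) {
    stop_vagcst("malformed registry line(s): expected 2 (synonym) or 3 ",
                "(taxon) tab-separated fields")
  }
  tx <- parts[nf == 3L]
  taxa <- data.frame(canonical = vapply(tx, `[[`, "", 1L),
                     rank = vapply(tx, `[[`, "", 2L),
                     group = vapply(tx, `[[`, "", 3L))
  sy <- parts[nf == 2L]
  synonyms <- stats::setNames(vapply(sy, `[[`, "", 2L),
                              vapply(sy, `[[`, "", 1L))
  new_taxon_registry(taxa, synonyms)
}

#' @rdname read_taxon_registry
#' @param registry a \code{taxon_registry} to serialize.
#' @export
write_taxon_registry <- function(registry, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("# vagcst taxon registry", con)
  writeLines("# canonical_name\trank\tgroup", con)
  writeLines(paste(registry$taxa$canonical, registry$taxa$rank,
                   registry$taxa$group, sep = "\t"), con)
  if (length(registry$synonyms)) {
    writeLines("# alias\tcanonical", con)
    writeLines(paste(names(registry$synonyms), unname(registry$synonyms),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' @export
print.taxon_registry <- function(x, ...) {
  cat("<taxon_registry>", nrow(x$taxa), "canonical taxa,",
      length(x$synonyms), "synonyms\n")
  print(table(x$taxa$group))
  invisible(x)
}
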