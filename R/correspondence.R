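#' Spot-to-reference correspondence tables
#'
#' Which (spot zone, reference label) combinations count as "right location".
#' The package ships the correspondence tables used in the two field
#' validations of the camera: `"study1_sound"` (spot zones vs audible-sound
#' labels, first validation), `"study2_sound"` and `"study2_behaviour"`
#' (second validation, where behaviour was scored as well). Users can supply
#' their own table with the same columns (`zone`, `label`).
#'
#' @param name one of `"study1_sound"`, `"study2_sound"`, `"study2_behaviour"`,
#'   or a path to a CSV with columns `zone,label`
#' @return object of class `fc_correspondence`: data frame of accepted pairs
#' @examples
#' tab <- correspondence_table("study1_sound")
#' is_location_correct("trough", "trough", tab)
#' @export
correspondence_table <- function(name = "study1_sound") {
  builtin <- c(study1_sound = "correspondence_study1_sound.csv",
               study2_sound = "correspondence_study2_sound.csv",
               study2_behaviour = "correspondence_study2_behaviour.csv")
  path <- if (name %in% names(builtin)) {
    system.file("extdata", builtin[[name]], package = "farrowcam",
                mustWork = TRUE)
  } else name
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("zone", "label") %in% names(df)))
    stop("correspondence table needs columns zone,label")
  bad <- !df$zone %in% pen_zones()
  if (any(bad)) stop("unknown zone in correspondence table: ",
                     paste(unique(df$zone[bad]), collapse = ", "))
  structure(df[, c("zone", "label")], class = c("fc_correspondence",
                                                "data.frame"))
}

# Canonical label spelling. The simulator's behaviour states map onto the
# ethogram labels used in the correspondence tables.
normalise_label <- function(label) {
  lab <- tolower(gsub("[ /-]+", "_", trimws(label)))
  synonyms <- c(jute_rooting = "playing_with_sack",
                jute_sack_rooting = "playing_with_sack",
                sitting_standing = "standing",
                lying = "lying_down",
                sow_vocal = "sow_in_crate",
                neighbour = "neighbour_sow")
  hit <- lab %in% names(synonyms)
  lab[hit] <- synonyms[lab[hit]]
  lab
}

# Labels an event-log stream can carry after normalisation.
known_labels <- function() {
  c("sow_in_crate", "trough", "metal_fence", "neighbour_sow", "front_of_pen",
    "playing_with_sack", "eating", "standing", "moving_leg_lying",
    "lying_down", "none", "piglet_birth", "piglet_move", "background", "spot")
}

#' Is a spot at the right location for a reference event?
#'
#' Total lookup: any (zone, label) pair resolves to `TRUE` or `FALSE`;
#' unknown labels are rejected with a message.
#'
#' @param spot_zone zone of the spot (vectorised)
#' @param ref_label reference sound or behaviour label (vectorised)
#' @param table a [correspondence_table()]
#' @return logical vector
#' @export
is_location_correct <- function(spot_zone, ref_label,
                                table = correspondence_table("study1_sound")) {
  lab <- normalise_label(ref_label)
  bad <- !lab %in% known_labels()
  if (any(bad))
    stop("unknown reference label(s): ",
         paste(unique(ref_label[bad]), collapse = ", "))
  badz <- !spot_zone %in% pen_zones()
  if (any(badz))
    stop("unknown zone(s): ", paste(unique(spot_zone[badz]), collapse = ", "))
  key <- paste(spot_zone, lab, sep = "\r")
  ok <- paste(table$zone, normalise_label(table$label), sep = "\r")
  key %in% ok
}
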