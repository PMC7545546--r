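## shared fixture builders (everything generated in code; no stored data)

## a neutral-pose film with convenient round numbers
neutral_film <- function(anteversion = 30, inclination = 45, side = "left",
                         ...) {
  project_scene(cup_scene(anteversion, inclination, side = side, ...))
}

## random valid ellipses for property-style loops
random_ellipses <- function(n, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    a <- runif(1, 20, 150)
    ellipse2d(runif(1, 50, 450), runif(1, 50, 450),
              a = a, b = runif(1, 0.05, 1) * a,
              orientation_deg = runif(1, 0, 180))
  })
}

## study-condition parameter grid used by the recovery properties
scene_grid <- function(anteversion = c(5, 20, 40, 60),
                       inclination = c(30, 45, 60),
                       theta = c(-15, -5, 0, 5, 15),
                       phi = c(-10, 0, 10),
                       side = c("left", "right")) {
  expand.grid(anteversion = anteversion, inclination = inclination,
              theta = theta, phi = phi, side = side,
              stringsAsFactors = FALSE)
}

## minimal valid annotation list form (for IO schema tests)
demo_annotation <- function(film_id = "demo", side = "left") {
  film_annotation(project_scene(
    cup_scene(25, 42, side = side, film_id = film_id), n_rim_points = 16))
}
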