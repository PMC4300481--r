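# Shared builders for terse test records. All fixtures are built in code.

default_rs <- load_ruleset()

make_exam <- function(date = "2011-06-01", systolic = 110, diastolic = 70,
                      height = 170, weight = 63, waist = 80) {
  physical_exam(date, systolic, diastolic, height, weight, waist)
}

# A minimal valid person; age counted at 2011-12-31 with a mid-June birthday
# so completed age equals `age` on that date.
make_person <- function(id = "T001", sex = "male", age = 30,
                        family_history = list(), known_diseases = character(0),
                        smoking = "never", exams = list(make_exam()),
                        results = list(), visits = list(),
                        email = "t@example.org", phone = "+981234567",
                        treated_bp = FALSE) {
  person_record(
    person_id = id, name = paste("Test", id),
    birth_date = sprintf("%d-06-15", 2011 - age), sex = sex,
    email = email, phone = phone,
    history = medical_history(family_history = family_history,
                              known_diseases = known_diseases,
                              smoking_status = smoking,
                              treated_bp = treated_bp),
    exams = exams, results = results, visits = visits)
}

fh <- function(condition, relation = "mother", onset_age = NA_real_) {
  list(relation = relation, condition = condition, onset_age = onset_age)
}

rule_for <- function(ruleset, code, sex = NULL) {
  hits <- Filter(function(r) r$test_code == code &&
                   (is.null(sex) || r$target_sex %in% c("any", sex)),
                 ruleset$rules)
  hits[[1]]
}

# write a ruleset YAML from an R list and load it
load_ruleset_from <- function(doc) {
  path <- withr::local_tempfile(fileext = ".yaml",
                                .local_envir = parent.frame())
  yaml::write_yaml(doc, path)
  load_ruleset(path)
}

minimal_ruleset_doc <- function(rules) {
  list(version = "test-1",
       message_catalog = list(general_hello = "hello {name}",
                              due = "{test_code} due {due_date}"),
       rules = rules)
}

simple_rule <- function(test_code = "FPG", target_sex = "any", start_age = 45,
                        interval_days = 1095, ...) {
  c(list(test_code = test_code, target_sex = target_sex, start_age = start_age,
         interval_days = interval_days, messages = list("due")), list(...))
}
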