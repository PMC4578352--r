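{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "$id": "https://example.org/enm/schema/study-v1.json",
  "title": "Protocol application (study) document, version 1",
  "type": "object",
  "required": ["uuid", "substanceUuid", "protocol", "effects"],
  "properties": {
    "uuid": {"type": "string", "pattern": "^[A-Z0-9]{4}-[0-9a-f]{8}-[0-9a-f]{4}-[0-9a-f]{4}-[0-9a-f]{4}-[0-9a-f]{12}$"},
    "substanceUuid": {"type": "string"},
    "protocol": {
      "type": "object",
      "required": ["topcategory", "endpoint"],
      "properties": {
        "topcategory": {"enum": ["P-CHEM", "TOX", "ECOTOX", "ENV-FATE"]},
        "category": {"type": "string"},
        "endpoint": {"type": "string", "minLength": 1},
        "guideline": {"type": "array", "items": {"type": "string"}},
        "annotationIri": {"type": ["string", "null"]}
      }
    },
    "parameters": {"$ref": "#/definitions/valueMap"},
    "citation": {
      "type": "object",
      "properties": {
        "title": {"type": ["string", "null"]},
        "year": {"type": ["integer", "null"]},
        "owner": {"type": ["string", "null"]}
      }
    },
    "reliability": {
      "type": "object",
      "properties": {
        "value": {"enum": [1, 2, 3, 4, null]},
        "purposeFlag": {"type": ["string", "null"]},
        "studyResultType": {"type": ["string", "null"]}
      }
    },
    "effects": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "required": ["endpoint", "result"],
        "properties": {
          "endpoint": {"type": "string", "minLength": 1},
          "endpointIri": {"type": ["string", "null"]},
          "conditions": {"$ref": "#/definitions/valueMap"},
          "result": {
            "type": "object",
            "properties": {
              "loQualifier": {"type": ["string", "null"]},
              "loValue": {"type": ["number", "null"]},
              "upQualifier": {"type": ["string", "null"]},
              "upValue": {"type": ["number", "null"]},
              "errQualifier": {"type": ["string", "null"]},
              "errorValue": {"type": ["number", "null"]},
              "unit": {"type": "string"},
              "textValue": {"type": ["string", "null"]}
            }
          }
        }
      }
    }
  },
  "definitions": {
    "valueMap": {
      "type": "object",
      "additionalProperties": {
        "type": "object",
        "properties": {
          "value": {"type": ["number", "string", "null"]},
          "unit": {"type": "string"}
        }
      }
    }
  }
}
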