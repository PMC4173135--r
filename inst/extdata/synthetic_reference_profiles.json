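{
  "H": {
    "MW": {
      "o": 0.573466527143802,
      "a": 214.743032762401,
      "b": 328.078776871755,
      "c": 61.8169808448422,
      "max_value": 215.316499289545
    },
    "LogP": {
      "o": 0.0018214094829525,
      "a": 127.655925818828,
      "b": 3.02075951021193,
      "c": 0.994434430196859,
      "max_value": 127.657747228311
    },
    "HBA": {
      "o": 3.73833691123,
      "a": 601.564267899091,
      "b": 3.01173336683693,
      "c": 1.1990242796062,
      "max_value": 605.302604810321
    },
    "HBD": {
      "o": 0,
      "a": 988.456375055873,
      "b": 0.974774830837252,
      "c": 0.751416948118332,
      "max_value": 988.456375055873
    },
    "RB": {
      "o": 0.310760389593497,
      "a": 408.7443272073,
      "b": 4.99135838066228,
      "c": 1.79476775048542,
      "max_value": 409.055087596894
    },
    "arR": {
      "o": 0,
      "a": 902.980348273445,
      "b": 0.962415952983388,
      "c": 0.822736635359226,
      "max_value": 902.980348273445
    }
  },
  "I": {
    "MW": {
      "o": 0.136567663024736,
      "a": 136.149195383159,
      "b": 357.969836810053,
      "c": 69.2961390540025,
      "max_value": 136.285763046183
    },
    "LogP": {
      "o": 0.237289208075396,
      "a": 383.23216326263,
      "b": 4.98454613359817,
      "c": 1.21831570850598,
      "max_value": 383.469452470705
    },
    "HBA": {
      "o": 6.36014260477138,
      "a": 704.397428902855,
      "b": 2.00379961277963,
      "c": 1.00759505379223,
      "max_value": 710.757571507627
    },
    "HBD": {
      "o": 0,
      "a": 1926.1671183272,
      "b": -1.07874788381573,
      "c": 0.939723512864873,
      "max_value": 1926.1671183272
    },
    "RB": {
      "o": 0,
      "a": 364.997241503318,
      "b": 6.06559294011393,
      "c": 2.0205258007951,
      "max_value": 364.997241503318
    },
    "arR": {
      "o": 0,
      "a": 2079.32975372651,
      "b": -1.50647286381743,
      "c": 1.09844196213911,
      "max_value": 2079.32975372651
    }
  },
  "F": {
    "MW": {
      "o": 0.791712465565212,
      "a": 171.673773253347,
      "b": 297.86003943504,
      "c": 53.1661161644688,
      "max_value": 172.465485718912
    },
    "LogP": {
      "o": 0,
      "a": 211.042686641816,
      "b": 3.00359313123078,
      "c": 1.10684915774297,
      "max_value": 211.042686641816
    },
    "HBA": {
      "o": 0,
      "a": 707.487328768399,
      "b": 1.98230121523169,
      "c": 1.04789089063231,
      "max_value": 707.487328768399
    },
    "HBD": {
      "o": 0,
      "a": 1093.34794951476,
      "b": 0.968127805977268,
      "c": 0.687700081917627,
      "max_value": 1093.34794951476
    },
    "RB": {
      "o": 0,
      "a": 588.102128637782,
      "b": 1.99655873452303,
      "c": 1.27042066840311,
      "max_value": 588.102128637782
    },
    "arR": {
      "o": 0,
      "a": 909.603837320039,
      "b": 2.00668358795665,
      "c": 0.823685073963458,
      "max_value": 909.603837320039
    }
  }
}
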