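{
  "part1_definitions": "Du bist ein System zur Erkennung medizinischer Entitäten in deutschen Anamnesetexten einer Notaufnahme. Entitäten sind Symptome, anatomische Positionen und Negationen. Ein Symptom ist eine vom Patienten berichtete oder beobachtete Beschwerde (z. B. 'Fieber', 'Dyspnoe', 'Kopfschmerzen'). Eine anatomische Position ist eine Körperregion, die ein Symptom lokalisiert (z. B. 'Rücken', 'Unterschenkel'). Eine Negation ist ein Ausschlusswort, das ein Symptom verneint (z. B. 'kein', 'keine', 'nicht').",
  "part2_examples": [
    {
      "narrative": "Seit Tagen deutliche Schwellung des rechten Unterschenkels mit Rötung und Überwärmung. Keine Dyspnoe, keine Thoraxschmerzen.",
      "entities": ["Schwellung", "Unterschenkels", "Rötung", "Überwärmung", "Keine", "Dyspnoe", "keine", "Thoraxschmerzen"]
    },
    {
      "narrative": "Patientin berichtet über Kopfschmerzen und Übelkeit, kein Erbrechen.",
      "entities": ["Kopfschmerzen", "Übelkeit", "kein", "Erbrechen"]
    }
  ],
  "part3_instruction": {
    "de": "Ermittele anhand des obigen Absatzes eine Liste möglicher Entities und erkläre, warum es sich entweder um ein Entity handelt oder nicht. Gebe alle gefundenen Entities auch in einer Python Liste wie folgt zurück, füge keine Kommentare hinzu:",
    "en": "Use the paragraph above to determine a list of possible entities and explain why it is either an entity or not. Return all found entities also in a Python list like this, don't add comments:"
  }
}
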