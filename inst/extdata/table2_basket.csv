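"group","subgroup","item","grams_consume","fti","grams_purchase_printed"
"Whole Grains","Rice, Wheat, Corn, and Others","Rice",28.14,2.5,11.26
"Whole Grains","Rice, Wheat, Corn, and Others","Bread",204.33,1,204.33
"Whole Grains","Rice, Wheat, Corn, and Others","Spaghetti",17.52,2.36,7.43
"Tubers or Starchy Vegetables","Potatoes and Cassava","Potato",100,1.04,96.15
"Vegetables","All Types of Vegetables","Tomatoes",67.72,0.83,81.59
"Vegetables","All Types of Vegetables","Onion",39.77,0.78,50.99
"Vegetables","All Types of Vegetables","Lemon",33.22,0.58,57.27
"Vegetables","All Types of Vegetables","Carrot",28.17,0.94,29.97
"Vegetables","All Types of Vegetables","Avocado",26.86,0.73,36.8
"Vegetables","All Types of Vegetables","Corn",26.68,1.04,25.65
"Vegetables","All Types of Vegetables","Lettuce",25.77,1,25.77
"Vegetables","All Types of Vegetables","Sweet Pumpkin",17.19,0.7622,22.55
"Vegetables","All Types of Vegetables","Bell Pepper",5.84,0.86,6.79
"Vegetables","All Types of Vegetables","Chard",5.28,1.0192,5.18
"Vegetables","All Types of Vegetables","Zucchini",4.87,0.931,5.23
"Vegetables","All Types of Vegetables","Cucumber",4.82,0.76,6.34
"Vegetables","All Types of Vegetables","Green Beans",2.79,0.98,2.85
"Vegetables","All Types of Vegetables","Garlic",2.69,0.87,3.09
"Vegetables","All Types of Vegetables","Beetroot",2.19,0.7812,2.81
"Vegetables","All Types of Vegetables","Spinach",1.88,0.97,1.94
"Vegetables","All Types of Vegetables","Cauliflower",1.8,0.93,1.94
"Vegetables","All Types of Vegetables","Artichoke",1.12,1.17,0.96
"Vegetables","All Types of Vegetables","Mushrooms",0.94,0.62,1.52
"Vegetables","All Types of Vegetables","Asparagus",0.4,0.6405,0.62
"Fruits","All Types of Fruits","Banana",86.41,0.66,130.92
"Fruits","All Types of Fruits","Apple",54.84,0.83,66.07
"Fruits","All Types of Fruits","Orange",37.73,0.73,51.69
"Fruits","All Types of Fruits","Peach and Nectarines",22.59,0.75,30.12
"Fruits","All Types of Fruits","Grapes",18.34,0.92,19.93
"Fruits","All Types of Fruits","Mandarins",16.89,0.66,25.59
"Fruits","All Types of Fruits","Strawberry",14.06,0.92,15.28
"Fruits","All Types of Fruits","Melons",13.95,0.52,26.83
"Fruits","All Types of Fruits","Pears",11.71,0.85,13.78
"Fruits","All Types of Fruits","Kiwi",6.5,0.82,7.92
"Fruits","All Types of Fruits","Watermelon",5.14,0.52,9.88
"Fruits","All Types of Fruits","Cherry",3.58,0.84,4.27
"Fruits","All Types of Fruits","Plum",2.33,0.95,2.45
"Fruits","All Types of Fruits","Prickly Pear",1.67,0.95,1.76
"Fruits","All Types of Fruits","Cucumber",1.64,0.85,1.93
"Fruits","All Types of Fruits","Mango",1.44,0.71,2.03
"Fruits","All Types of Fruits","Apricot",0.53,0.95,0.56
"Fruits","All Types of Fruits","Grapefruit",0.4,0.68,0.59
"Fruits","All Types of Fruits","Cherimoya",0.25,1,0.25
"Dairy Products","Whole Milk or Equivalents","Whole Milk",400,1,400
"Protein Sources","Beef, Lamb, and Pork","Ground Beef",4.99,0.6,8.32
"Protein Sources","Beef, Lamb, and Pork","Pork Chop",3.37,0.5609,6
"Protein Sources","Beef, Lamb, and Pork","Black Beef",2.7,0.64,4.21
"Protein Sources","Beef, Lamb, and Pork","Pork Pulp",1.95,0.73,2.67
"Protein Sources","Beef, Lamb, and Pork","Pork Ribs",1,0.286,3.49
"Protein Sources","Chicken and Other Poultry","Chicken Thigh",17.81,0.5544,32.12
"Protein Sources","Chicken and Other Poultry","Chicken Breast",8.33,0.5928,14.04
"Protein Sources","Chicken and Other Poultry","Whole Chicken",2.55,0.507,5.02
"Protein Sources","Chicken and Other Poultry","Turkey Thigh",0.17,0.672,0.25
"Protein Sources","Chicken and Other Poultry","Turkey Breast",0.12,0.79,0.15
"Protein Sources","Chicken and Other Poultry","Ground Turkey",0.03,0.79,0.04
"Protein Sources","Eggs","Egg",15,0.9944,15.08
"Protein Sources","Fish","Hake",14.98,0.3871,38.69
"Protein Sources","Fish","Pomfret",11.18,0.4543,24.61
"Protein Sources","Fish","Salmon",1.84,0.89,2.07
"Protein Sources","Legumes","Dried Beans",67.6,1.4,48.28
"Protein Sources","Legumes","Lentils",32.4,1.6,20.25
"Added Fats","Unsaturated Oils","Vegetable Oil",19.55,1,19.55
"Added Fats","Unsaturated Oils","Olive Oil",0.45,1,0.45
"Added Fats","Saturated Oils","Butter",11.8,1,11.8
"Added Sugars","All Types of Sugars","Sugar",31,1,31
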